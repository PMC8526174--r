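#' Validate a structural-connectivity adjacency matrix
#'
#' All dynamics in this package run on simple undirected graphs encoded as
#' binary symmetric adjacency matrices with a zero diagonal. `as_adjacency()`
#' checks these invariants and returns the matrix as integer 0/1.
#'
#' @param A square numeric matrix.
#' @param require_edge require at least one edge (needed for dynamics use).
#' @return integer 0/1 matrix with zero diagonal.
#' @export
as_adjacency <- function(A, require_edge = FALSE) {
  if (!is.matrix(A) || nrow(A) != ncol(A)) {
    stop("adjacency matrix must be square", call. = FALSE)
  }
  if (any(!is.finite(A))) stop("adjacency matrix must be finite", call. = FALSE)
  if (any(A != 0 & A != 1)) {
    stop("adjacency matrix entries must be 0 or 1", call. = FALSE)
  }
  if (any(diag(A) != 0)) stop("adjacency matrix must have a zero diagonal", call. = FALSE)
  if (!isTRUE(all.equal(A, t(A), check.attributes = FALSE))) {
    stop("adjacency matrix must be symmetric", call. = FALSE)
  }
  if (require_edge && sum(A) == 0) {
    stop("graph must contain at least one edge", call. = FALSE)
  }
  storage.mode(A) <- "integer"
  dimnames(A) <- NULL
  A
}

#' Number of undirected edges of an adjacency matrix
#' @param A adjacency matrix (see [as_adjacency()]).
#' @return integer edge count.
#' @export
n_edges <- function(A) as.integer(sum(A) / 2)

#' Degree sequence of an adjacency matrix
#' @param A adjacency matrix.
#' @return integer vector of node degrees (row sums).
#' @export
degrees <- function(A) as.integer(rowSums(A))

# edge list (m x 2, u < v) of an adjacency matrix
edge_list <- function(A) {
  idx <- which(upper.tri(A) & A == 1L, arr.ind = TRUE)
  colnames(idx) <- NULL
  idx
}

# adjacency <-> igraph
adj_to_igraph <- function(A) {
  igraph::graph_from_adjacency_matrix(A, mode = "undirected", diag = FALSE)
}

igraph_to_adj <- function(g) {
  A <- as.matrix(igraph::as_adjacency_matrix(g, type = "both", sparse = FALSE))
  A[A > 1] <- 1
  as_adjacency(A)
}

#' Read a graph from file
#'
#' Supported formats: two-column edge-list TSV (optional header; 0-based node
#' labels are detected and shifted to 1-based), square adjacency CSV, and
#' GraphML. The format is inferred from the file extension unless given.
#'
#' @param path file path.
#' @param format one of `"auto"`, `"edgelist"`, `"csv"`, `"graphml"`.
#' @return adjacency matrix (see [as_adjacency()]).
#' @export
read_graph_file <- function(path, format = c("auto", "edgelist", "csv", "graphml")) {
  format <- match.arg(format)
  if (format == "auto") {
    ext <- tolower(tools::file_ext(path))
    format <- switch(ext,
      "graphml" = "graphml",
      "csv" = "csv",
      "tsv" = "edgelist", "txt" = "edgelist", "edges" = "edgelist",
      stop("cannot infer graph format from extension '", ext, "'", call. = FALSE)
    )
  }
  if (format == "graphml") {
    return(igraph_to_adj(igraph::read_graph(path, format = "graphml")))
  }
  if (format == "csv") {
    M <- as.matrix(utils::read.csv(path, header = FALSE))
    dimnames(M) <- NULL
    return(as_adjacency(M))
  }
  # edge list
  first <- readLines(path, n = 1L)
  has_header <- !grepl("^\\s*[0-9]+[\\s,\t]+[0-9]+\\s*$", first, perl = TRUE)
  el <- utils::read.table(path, header = has_header)
  if (ncol(el) < 2L) stop("edge list needs two columns", call. = FALSE)
  el <- as.matrix(el[, 1:2])
  if (min(el) == 0L) el <- el + 1L # 0-based labels on disk
  n <- max(el)
  A <- matrix(0L, n, n)
  A[el] <- 1L
  A[el[, 2:1]] <- 1L
  diag(A) <- 0L
  as_adjacency(A)
}

#' Write a graph to file
#'
#' @param A adjacency matrix.
#' @param path output path; extension selects the format unless given.
#' @param format one of `"auto"`, `"edgelist"`, `"csv"`, `"graphml"`.
#' @param zero_based write edge-list node labels 0-based (default 1-based).
#' @return `path`, invisibly.
#' @export
write_graph_file <- function(A, path,
                             format = c("auto", "edgelist", "csv", "graphml"),
                             zero_based = FALSE) {
  A <- as_adjacency(A)
  format <- match.arg(format)
  if (format == "auto") {
    ext <- tolower(tools::file_ext(path))
    format <- switch(ext,
      "graphml" = "graphml",
      "csv" = "csv",
      "tsv" = "edgelist", "txt" = "edgelist", "edges" = "edgelist",
      stop("cannot infer graph format from extension '", ext, "'", call. = FALSE)
    )
  }
  if (format == "graphml") {
    igraph::write_graph(adj_to_igraph(A), path, format = "graphml")
  } else if (format == "csv") {
    utils::write.table(A, path, sep = ",", row.names = FALSE, col.names = FALSE)
  } else {
    el <- edge_list(A)
    if (zero_based) el <- el - 1L
    utils::write.table(el, path, sep = "\t", row.names = FALSE,
                       col.names = c("from", "to"), quote = FALSE)
  }
  invisible(path)
}

is_connected_adj <- function(A) {
  igraph::is_connected(adj_to_igraph(A))
}
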