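#' Write / read a connectivity or adjacency matrix as labelled TSV
#'
#' Plain tab-delimited n x n matrix with a label header row and label
#' first column -- the interchange format used between pipeline stages.
#'
#' @param m Matrix with dimnames (e.g. a [connectivity_matrix()]).
#' @param path Output file.
#' @return `path`, invisibly.
#' @export
write_matrix_tsv <- function(m, path) {
  stopifnot(is.matrix(m))
  df <- data.frame(label = rownames(m), m, check.names = FALSE)
  utils::write.table(df, path, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}

#' @rdname write_matrix_tsv
#' @export
read_matrix_tsv <- function(path) {
  df <- utils::read.table(path, sep = "\t", header = TRUE, check.names = FALSE)
  m <- as.matrix(df[, -1L, drop = FALSE])
  rownames(m) <- df[[1L]]
  storage.mode(m) <- "double"
  m
}

#' Write / read an epoch array as TSV plus JSON sidecar
#'
#' The data file holds one row per epoch x node trace (columns `epoch`,
#' `node`, then one column per sample); the JSON sidecar records the
#' sampling rate, epoch start time and node labels.
#'
#' @param x An [epoch_array()].
#' @param prefix Path prefix; writes `<prefix>.tsv` and `<prefix>.json`.
#' @return `prefix`, invisibly.
#' @export
write_epochs <- function(x, prefix) {
  stopifnot(inherits(x, "epoch_array"))
  d <- x$data
  n_ep <- dim(d)[1L]; n_no <- dim(d)[2L]; n_sa <- dim(d)[3L]
  flat <- matrix(aperm(d, c(3L, 2L, 1L)), nrow = n_ep * n_no, byrow = TRUE)
  df <- data.frame(epoch = rep(seq_len(n_ep), each = n_no),
                   node = rep(x$labels, times = n_ep), flat)
  utils::write.table(df, paste0(prefix, ".tsv"), sep = "\t", quote = FALSE,
                     row.names = FALSE)
  jsonlite::write_json(list(fs_hz = x$fs_hz, t0_s = x$t0_s, labels = x$labels,
                            n_epochs = n_ep, n_nodes = n_no, n_samples = n_sa),
                       paste0(prefix, ".json"), auto_unbox = TRUE, digits = NA)
  invisible(prefix)
}

#' @rdname write_epochs
#' @export
read_epochs <- function(prefix) {
  meta <- jsonlite::read_json(paste0(prefix, ".json"), simplifyVector = TRUE)
  df <- utils::read.table(paste0(prefix, ".tsv"), sep = "\t", header = TRUE)
  flat <- as.matrix(df[, -(1:2), drop = FALSE])
  d <- aperm(array(t(flat), dim = c(meta$n_samples, meta$n_nodes, meta$n_epochs)),
             c(3L, 2L, 1L))
  epoch_array(d, fs_hz = meta$fs_hz, t0_s = meta$t0_s, labels = meta$labels)
}
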