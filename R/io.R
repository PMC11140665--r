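#' Write / read a tab-delimited session table
#'
#' @param table Session table.
#' @param path File path.
#' @return `read_session_table()` returns the data.frame.
#' @export
write_session_table <- function(table, path) {
  utils::write.table(table, path, sep = "\t", quote = FALSE,
                     row.names = FALSE)
  invisible(path)
}

#' @rdname write_session_table
#' @export
read_session_table <- function(path) {
  utils::read.delim(path, stringsAsFactors = FALSE)
}

#' Write / read a parcellation lookup (tab-delimited)
#'
#' @param parcellation Parcellation data.frame.
#' @param path File path.
#' @export
write_parcellation <- function(parcellation, path) {
  utils::write.table(parcellation, path, sep = "\t", quote = FALSE,
                     row.names = FALSE)
  invisible(path)
}

#' @rdname write_parcellation
#' @export
read_parcellation <- function(path) {
  utils::read.delim(path, stringsAsFactors = FALSE)
}

#' Write / read a numeric matrix as tab-delimited text
#'
#' @param m Matrix.
#' @param path File path.
#' @export
write_matrix_tsv <- function(m, path) {
  utils::write.table(m, path, sep = "\t", quote = FALSE,
                     row.names = FALSE, col.names = FALSE)
  invisible(path)
}

#' @rdname write_matrix_tsv
#' @export
read_matrix_tsv <- function(path) {
  as.matrix(utils::read.delim(path, header = FALSE))
}

#' Write an edgewise map as a tidy table plus JSON metadata
#'
#' @param map A thresholded edgewise map.
#' @param path Output TSV path; metadata goes to `<path>.json`.
#' @export
write_edgewise_map <- function(map, path) {
  n <- map$n_nodes
  idx <- edge_index(n)
  tab <- data.frame(edge_i = idx$i, edge_j = idx$j,
                    beta_z = map$beta_z, t = map$t, p = map$p,
                    q = map$q_value,
                    display_mask = map$display_mask,
                    strength_mask = map$strength_mask)
  utils::write.table(tab, path, sep = "\t", quote = FALSE, row.names = FALSE)
  meta <- list(n_nodes = n, n_sessions = map$n_sessions, B = map$B,
               seed = map$seed, exhaustive = map$exhaustive,
               p_alpha = map$p_alpha, q = map$q,
               covariates = map$covariate_names)
  jsonlite::write_json(meta, paste0(path, ".json"),
                       auto_unbox = TRUE, digits = NA, null = "null")
  invisible(path)
}
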