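#' Write a flux solution as a TSV table
#'
#' Two columns (`reaction_id`, `flux`), rows sorted lexicographically by id,
#' fluxes at 6 significant digits — a deterministic, diffable format for
#' regression comparisons.
#'
#' @param solution an optimal `flux_solution`.
#' @param path output file.
#' @return `path`, invisibly.
#' @export
write_flux_table <- function(solution, path) {
  stopifnot(inherits(solution, "flux_solution"))
  if (solution$status != "optimal")
    stop("cannot write a flux table for a ", solution$status, " solution")
  v <- solution$fluxes[order(names(solution$fluxes), method = "radix")]
  df <- data.frame(reaction_id = names(v),
                   flux = formatC(signif(v, 6), format = "g", digits = 6),
                   stringsAsFactors = FALSE)
  utils::write.table(df, path, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}

#' Read a flux table written by [write_flux_table()]
#' @param path TSV file.
#' @return named numeric vector of fluxes.
#' @export
read_flux_table <- function(path) {
  df <- utils::read.table(path, sep = "\t", header = TRUE,
                          stringsAsFactors = FALSE)
  stats::setNames(as.numeric(df$flux), df$reaction_id)
}

#' Write an energetics table as TSV (rows = quantities, columns = scenarios)
#' @param table output of [energetics_table()].
#' @param path output file.
#' @return `path`, invisibly.
#' @export
write_energetics_table <- function(table, path) {
  out <- cbind(data.frame(quantity = rownames(table), stringsAsFactors = FALSE),
               signif(table, 6))
  utils::write.table(out, path, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}
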