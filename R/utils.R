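#' Derive a deterministic sub-stream seed from a master seed
#'
#' All randomness in the package flows from one master seed; each stage draws
#' its own seed with a stage label so stages can be rerun in isolation and the
#' full pipeline stays reproducible.
#'
#' @param master_seed integer master seed.
#' @param label character stage label.
#' @return integer seed in \[1, 2^31 - 2].
#' @export
derive_seed <- function(master_seed, label) {
  stopifnot(is.numeric(master_seed), length(master_seed) == 1L,
            is.character(label), length(label) == 1L)
  h <- sum(utf8ToInt(label) * seq_along(utf8ToInt(label)) * 131)
  as.integer((abs(master_seed) + h) %% 2147483646 + 1)
}

#' Write a result table as TSV (header row, floats at 6 significant digits)
#'
#' @param df data.frame to write.
#' @param path output path.
#' @param comment optional comment lines written with a leading `#`.
#' @export
write_tsv_table <- function(df, path, comment = NULL) {
  num <- vapply(df, is.double, logical(1))
  df[num] <- lapply(df[num], function(x) signif(x, 6))
  con <- file(path, open = "wt")
  on.exit(close(con))
  if (!is.null(comment)) writeLines(paste0("# ", comment), con)
  utils::write.table(df, con, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}

#' Read a TSV table written by [write_tsv_table()]
#' @param path input path.
#' @return data.frame.
#' @export
read_tsv_table <- function(path) {
  utils::read.delim(path, comment.char = "#", stringsAsFactors = FALSE,
                    check.names = FALSE)
}

# Population (divide-by-n) standard deviation.
pop_sd <- function(x) {
  m <- mean(x)
  sqrt(mean((x - m)^2))
}

# Circular distance between hours a and b on a cycle of length `period`.
circ_dist <- function(a, b, period) {
  d <- abs(a - b) %% period
  pmin(d, period - d)
}

#' Circular median of phases on a cycle
#'
#' Minimizer, over the observed phases, of the summed circular distances to all
#' phases; ties broken toward the smaller value.
#'
#' @param phases numeric phases in hours.
#' @param period cycle length in hours.
#' @return scalar circular median phase.
#' @export
circular_median <- function(phases, period = 24) {
  stopifnot(length(phases) >= 1)
  if (length(phases) == 1L) return(phases)
  cost <- vapply(phases, function(p) sum(circ_dist(p, phases, period)),
                 numeric(1))
  cand <- phases[cost == min(cost)]
  min(cand)
}
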