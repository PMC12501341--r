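logit <- function(p) log(p / (1 - p))

invlogit <- function(x) 1 / (1 + exp(-x))

#' Round half away from zero
#'
#' Base `round()` rounds half to even; descriptive tables here follow the
#' half-up convention (10.75 -> 10.8 at one decimal).
#'
#' @param x numeric vector.
#' @param digits number of decimal places.
#' @return rounded numeric vector.
#' @export
round_half_up <- function(x, digits = 1) {
  scale <- 10^digits
  sign(x) * floor(abs(x) * scale + 0.5) / scale
}

#' Format a count as a percentage string
#'
#' @param num numerator count.
#' @param den denominator count.
#' @param digits decimal places (default 1, table convention).
#' @return character vector like `"52.8"`.
#' @export
fmt_pct <- function(num, den, digits = 1) {
  sprintf(paste0("%.", digits, "f"), round_half_up(100 * num / den, digits))
}

star_flags <- function(p, thresholds = c(0.001, 0.005, 0.05)) {
  out <- rep("", length(p))
  out[!is.na(p) & p < thresholds[3]] <- "*"
  out[!is.na(p) & p < thresholds[2]] <- "**"
  out[!is.na(p) & p < thresholds[1]] <- "***"
  out
}

# Deterministic child seeds below 2^31 derived from a master seed.
derive_seed <- function(seed, offset) {
  ((as.numeric(seed) + 104729 * as.numeric(offset)) %% 2147483587) + 1
}

demrisk_file <- function(...) {
  system.file(..., package = "demrisk", mustWork = TRUE)
}
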