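# Internal helpers shared across modules.

RNASES <- c("III", "J1", "Y")

# condition label used for each RNase's depletion strain
RNASE_CONDITION <- c(III = "rnc", J1 = "rnjA", Y = "rny")
CONDITION_RNASE <- c(rnc = "III", rnjA = "J1", Y = "Y", rny = "Y")

`%||%` <- function(a, b) if (is.null(a)) b else a

stopf <- function(fmt, ...) stop(sprintf(fmt, ...), call. = FALSE)
warnf <- function(fmt, ...) warning(sprintf(fmt, ...), call. = FALSE)

#' @keywords internal
assert_scalar_number <- function(x, name, lower = -Inf, upper = Inf) {
  if (!is.numeric(x) || length(x) != 1L || !is.finite(x) || x < lower || x > upper)
    stopf("'%s' must be a single finite number in [%s, %s]", name, lower, upper)
  invisible(x)
}

# Columns of a sample metadata data.frame that identify the four main
# experiments: wild type plus the three depletion strains grown without IPTG.
is_main_sample <- function(samples) {
  samples$condition == "wt" |
    (samples$condition %in% RNASE_CONDITION & samples$iptg == "minus")
}

# Main-condition label per sample ("wt", "rnc", "rnjA", "rny"), NA for others.
main_condition <- function(samples) {
  out <- rep(NA_character_, nrow(samples))
  main <- is_main_sample(samples)
  out[main] <- samples$condition[main]
  out
}

# deterministic seed derivation, kept below 2^31
derive_seed <- function(seed, k) {
  (as.integer(seed) * 1009L + as.integer(k)) %% 2147483647L
}
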