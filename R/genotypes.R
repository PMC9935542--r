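#' Summarize a SNP genotype count table
#'
#' Computes the minor (C) allele frequency, the observed genotype
#' fractions, and the genotype fractions expected under Hardy-Weinberg
#' equilibrium (q^2, 2pq, p^2 with p the C-allele frequency). Fractions
#' are returned both raw and rounded to 0.1 percentage points for display,
#' matching the conventional reporting precision.
#'
#' @param counts named numeric vector with elements \code{TT}, \code{TC},
#'   \code{CC}: the number of wildtype-homozygous, heterozygous, and
#'   C-homozygous subjects.
#' @return An object of class \code{genotype_summary}: a list with
#'   \code{counts}, \code{n}, \code{allele_freq_c},
#'   \code{observed_freq}, \code{hwe_expected_freq} (each a named vector
#'   summing to one), and \code{display} (percentages rounded to 0.1).
#' @examples
#' summarize_genotypes(c(TT = 76, TC = 59, CC = 11))
#' @export
summarize_genotypes <- function(counts) {
  need <- c("TT", "TC", "CC")
  if (!all(need %in% names(counts))) {
    stop("counts must be named with TT, TC, CC")
  }
  counts <- counts[need]
  if (any(counts < 0) || any(!is.finite(counts))) {
    stop("counts must be finite and non-negative")
  }
  n <- sum(counts)
  if (n == 0) stop("empty cohort")
  p <- unname((counts[["TC"]] + 2 * counts[["CC"]]) / (2 * n))
  observed <- counts / n
  expected <- c(TT = (1 - p)^2, TC = 2 * p * (1 - p), CC = p^2)
  out <- list(
    counts = counts,
    n = n,
    allele_freq_c = p,
    observed_freq = observed,
    hwe_expected_freq = expected,
    display = list(
      allele_freq_pct = round(100 * p, 1),
      observed_pct = round(100 * observed, 1),
      hwe_expected_pct = round(100 * expected, 1)))
  class(out) <- "genotype_summary"
  out
}

#' @export
print.genotype_summary <- function(x, ...) {
  cat("Genotype summary (n = ", x$n, ")\n", sep = "")
  cat("  C-allele frequency: ", x$display$allele_freq_pct, "%\n", sep = "")
  tab <- rbind(observed = x$display$observed_pct,
               `HWE expected` = x$display$hwe_expected_pct)
  print(tab)
  invisible(x)
}
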