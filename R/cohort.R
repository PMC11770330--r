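#' Domain summary z-scores
#'
#' Averages test-specific z-scores within each cognitive domain. Missing
#' tests are dropped (their count is reported); a domain with no valid test
#' yields `NA` and is flagged.
#'
#' @param test_z named list with one numeric vector of test z-scores per
#'   domain.
#' @return list with `domain_z` (named numeric), `n_tests`, `n_missing`,
#'   and `incomplete` (logical per domain).
#' @export
domain_summary <- function(test_z) {
  stop_if(!is.list(test_z) || length(test_z) == 0L,
          "test_z must be a nonempty list of per-domain score vectors")
  nm <- names(test_z) %||% paste0("domain_", seq_along(test_z))
  used <- vapply(test_z, function(v) sum(is.finite(v)), integer(1))
  miss <- vapply(test_z, function(v) sum(!is.finite(v)), integer(1))
  z <- vapply(test_z, function(v) {
    v <- v[is.finite(v)]
    if (length(v) == 0L) NA_real_ else mean(v)
  }, numeric(1))
  names(z) <- nm
  list(domain_z = z, n_tests = stats::setNames(used, nm),
       n_missing = stats::setNames(miss, nm), incomplete = is.na(z))
}

#' Classify post-stroke cognitive impairment from domain z-scores
#'
#' A participant is impaired when at least one domain summary z-score is at
#' or below the threshold (default -1.5, i.e. 1.5 SD below the norm).
#' Missing domains make the status undefined (`NA`).
#'
#' @param domain_z numeric vector of domain summary z-scores.
#' @param threshold impairment threshold (inclusive).
#' @return 1 (impaired), 0, or `NA` when any domain is missing.
#' @examples
#' psci_classify(c(-1.6, 0, 0, 0))             # 1
#' psci_classify(rep(-1.5, 4))                 # 1 (boundary inclusive)
#' @export
psci_classify <- function(domain_z, threshold = -1.5) {
  if (any(!is.finite(domain_z))) return(NA_integer_)
  as.integer(min(domain_z) <= threshold)
}

#' Cross-classification of impairment status at two timepoints
#'
#' Tabulates paired binary PSCI status at months 6 and 36 into the four
#' cells of a transition table, the marginal impaired counts at each
#' timepoint, and the number of converters (participants whose status
#' changed in either direction).
#'
#' @param psci6,psci36 paired binary vectors (0/1; pairs with any `NA` are
#'   dropped and counted in `n_dropped`).
#' @return a `transition_table`: list with `both`, `six_only`,
#'   `thirtysix_only`, `neither`, `month6_total`, `month36_total`,
#'   `converters`, `n`, `n_dropped`.
#' @export
transition_table <- function(psci6, psci36) {
  stop_if(length(psci6) != length(psci36),
          "timepoint vectors must have the same length")
  ok <- !is.na(psci6) & !is.na(psci36)
  a <- as.integer(psci6[ok]); b <- as.integer(psci36[ok])
  stop_if(!all(a %in% 0:1) || !all(b %in% 0:1),
          "PSCI status must be binary (0/1)")
  out <- list(
    both = sum(a == 1 & b == 1),
    six_only = sum(a == 1 & b == 0),
    thirtysix_only = sum(a == 0 & b == 1),
    neither = sum(a == 0 & b == 0),
    n = sum(ok),
    n_dropped = sum(!ok)
  )
  out$month6_total <- out$both + out$six_only
  out$month36_total <- out$both + out$thirtysix_only
  out$converters <- out$six_only + out$thirtysix_only
  structure(out, class = "transition_table")
}

#' @export
print.transition_table <- function(x, ...) {
  cat("PSCI transition table (month 6 -> month 36)\n")
  cat(sprintf("  impaired at both:        %4d\n", x$both))
  cat(sprintf("  month 6 only:            %4d\n", x$six_only))
  cat(sprintf("  month 36 only:           %4d\n", x$thirtysix_only))
  cat(sprintf("  unimpaired at both:      %4d\n", x$neither))
  cat(sprintf("  impaired month 6 / 36:   %4d / %d of %d\n",
              x$month6_total, x$month36_total, x$n))
  cat(sprintf("  converters:              %4d\n", x$converters))
  invisible(x)
}
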