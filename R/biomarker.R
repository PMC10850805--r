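# Genetic biomarkers of dependency: the effect-size-gated
# mutation-dependency screen, dependency-expression/copy-number
# correlation, GISTIC classification, co-amplification frequency,
# amplicon stratification, and survival comparison.

#' Flag mutation status of one gene across cell lines
#'
#' A line is `mutant` when it carries at least one record for the gene
#' with the hotspot or damaging flag set; `wildtype` when it appears in
#' the mutation table (for any gene) but has no flagged record for this
#' one; `unknown` when the line is absent from the table entirely
#' (excluded downstream — unknown status is never defaulted to wildtype).
#'
#' @param mutations Mutation data.frame from [read_mutations()].
#' @param gene Gene symbol (or `gene_id`).
#' @param lines Character vector of line ids to flag.
#' @return Named character vector in `mutant`/`wildtype`/`unknown`.
#' @export
mutation_flag <- function(mutations, gene, lines) {
  sym <- if (inherits(gene, "gene_id")) gene$symbol else
    parse_gene_label(gene)$symbol
  profiled <- unique(as.character(mutations$line_id))
  hits <- mutations$gene == sym &
    (mutations$is_hotspot | mutations$is_damaging)
  mutant <- unique(as.character(mutations$line_id[hits]))
  out <- ifelse(lines %in% mutant, "mutant",
                ifelse(lines %in% profiled, "wildtype", "unknown"))
  names(out) <- lines
  out
}

#' Test one mutation-dependency association
#'
#' Welch two-sample t-test of the gene-effect values in mutant vs
#' wildtype lines, with Cohen's d (pooled SD, oriented
#' mutant-minus-wildtype). The association is flagged significant when
#' `p < alpha` and `|d| >= d_gate` — the effect-size gate replaces
#' multiple-testing correction in the screen.
#'
#' @param effect_vector Named numeric vector (line -> gene effect).
#' @param flags Named character vector from [mutation_flag()].
#' @param alpha,d_gate Significance gates (defaults 0.05 and 1).
#' @param pooled Use Student's pooled t instead of Welch.
#' @return An `association_result`: list with group sizes and means, `t`,
#'   `df`, `p_value`, `cohens_d`, `significant`.
#' @export
associate <- function(effect_vector, flags, alpha = 0.05, d_gate = 1,
                      pooled = FALSE) {
  common <- intersect(names(effect_vector)[!is.na(effect_vector)],
                      names(flags)[flags != "unknown"])
  mut <- effect_vector[common[flags[common] == "mutant"]]
  wt <- effect_vector[common[flags[common] == "wildtype"]]
  if (length(mut) < 2L || length(wt) < 2L) {
    stop("insufficient group: need >= 2 mutant and >= 2 wildtype lines ",
         sprintf("(got %d/%d)", length(mut), length(wt)), call. = FALSE)
  }
  tt <- welch_t(mut, wt, pooled = pooled)
  d <- cohens_d(mut, wt)
  structure(list(n_mutant = length(mut), n_wildtype = length(wt),
                 mean_mutant = mean(mut), mean_wildtype = mean(wt),
                 t_statistic = tt$statistic, df = tt$df,
                 p_value = tt$p_value, cohens_d = d,
                 significant = tt$p_value < alpha && abs(d) >= d_gate),
            class = "association_result")
}

#' @export
print.association_result <- function(x, ...) {
  cat(sprintf("<association> n = %d mut / %d wt, d = %.3g, p = %.3g%s\n",
              x$n_mutant, x$n_wildtype, x$cohens_d, x$p_value,
              if (x$significant) " *" else ""))
  invisible(x)
}

#' Screen targets x mutation biomarkers for dependency associations
#'
#' Runs [associate()] over the full grid of prioritized dependency genes
#' against candidate biomarker genes. Biomarkers mutated in fewer than
#' `min_prevalence` of flagged lines are excluded up front. No
#' multiple-testing correction is applied beyond the effect-size gate
#' (a Benjamini-Hochberg column is emitted for information only).
#'
#' @param effect A `screen_matrix` with role `"effect"`.
#' @param targets `gene_set` (or character) of dependency genes.
#' @param biomarker_genes `gene_set` (or character) of candidate mutated
#'   genes.
#' @param mutations Mutation data.frame from [read_mutations()].
#' @param min_prevalence Minimum mutant fraction among profiled lines
#'   (default 0.05).
#' @param alpha,d_gate Passed to [associate()].
#' @return data.frame, one row per tested (target, biomarker) pair, with
#'   an extra `p_bh` column; attribute `"excluded_biomarkers"` lists
#'   prevalence-filtered genes and `"skipped"` counts group-size failures.
#' @export
association_screen <- function(effect, targets, biomarker_genes, mutations,
                               min_prevalence = 0.05, alpha = 0.05,
                               d_gate = 1) {
  stopifnot(inherits(effect, "screen_matrix"))
  lines <- rownames(effect)
  flags_by_bm <- list()
  excluded <- character(0)
  for (bm in as.character(biomarker_genes)) {
    fl <- mutation_flag(mutations, bm, lines)
    known <- fl[fl != "unknown"]
    prev <- if (length(known)) mean(known == "mutant") else 0
    if (prev < min_prevalence) {
      excluded <- c(excluded, bm)
    } else {
      flags_by_bm[[bm]] <- fl
    }
  }
  rows <- list(); skipped <- 0L
  for (target in intersect(as.character(targets), colnames(effect))) {
    ev <- unclass(effect)[, target]
    for (bm in names(flags_by_bm)) {
      res <- tryCatch(associate(ev, flags_by_bm[[bm]], alpha = alpha,
                                d_gate = d_gate),
                      error = function(e) NULL)
      if (is.null(res)) { skipped <- skipped + 1L; next }
      rows[[length(rows) + 1L]] <- data.frame(
        target = target, biomarker = bm,
        n_mutant = res$n_mutant, n_wildtype = res$n_wildtype,
        mean_mutant = res$mean_mutant, mean_wildtype = res$mean_wildtype,
        t_statistic = res$t_statistic, p_value = res$p_value,
        cohens_d = res$cohens_d, significant = res$significant,
        stringsAsFactors = FALSE)
    }
  }
  out <- if (length(rows)) do.call(rbind, rows) else
    data.frame(target = character(0), biomarker = character(0),
               n_mutant = integer(0), n_wildtype = integer(0),
               mean_mutant = numeric(0), mean_wildtype = numeric(0),
               t_statistic = numeric(0), p_value = numeric(0),
               cohens_d = numeric(0), significant = logical(0))
  out$p_bh <- if (nrow(out)) stats::p.adjust(out$p_value, "BH") else numeric(0)
  rownames(out) <- NULL
  attr(out, "excluded_biomarkers") <- excluded
  attr(out, "skipped") <- skipped
  out
}

#' Correlate dependency with an expression / copy-number covariate
#'
#' Pearson r over pairwise-complete (line) values with a two-sided p from
#' the t distribution on n - 2 degrees of freedom.
#'
#' @param effect_vector,covariate_vector Named numeric vectors (joined on
#'   names when present, positionally otherwise).
#' @return A `vp_test` (see [pearson_cor()]).
#' @export
dependency_covariate_correlation <- function(effect_vector,
                                             covariate_vector) {
  if (!is.null(names(effect_vector)) && !is.null(names(covariate_vector))) {
    common <- intersect(names(effect_vector), names(covariate_vector))
    effect_vector <- effect_vector[common]
    covariate_vector <- covariate_vector[common]
  }
  pearson_cor(effect_vector, covariate_vector)
}

GISTIC_LEVELS <- c("deep_deletion", "loss", "diploid", "gain",
                   "amplification")

#' Classify discrete GISTIC copy-number codes
#'
#' Maps the 5-level code to its label: -2 deep deletion, -1 loss,
#' 0 diploid, +1 gain, +2 amplification. The "copy gain" predicate used
#' for gain-frequency summaries is code >= 1.
#'
#' @param code Integer vector with values in -2..2 (`NA` passed through).
#' @return Factor with levels `deep_deletion < loss < diploid < gain <
#'   amplification`.
#' @export
classify_gistic <- function(code) {
  bad <- !is.na(code) & !(code %in% -2:2)
  if (any(bad)) {
    stop("GISTIC codes outside {-2,...,2}: ",
         paste(unique(code[bad]), collapse = ", "), call. = FALSE)
  }
  factor(GISTIC_LEVELS[code + 3L], levels = GISTIC_LEVELS, ordered = TRUE)
}

#' Co-amplification frequency with an anchor gene
#'
#' Among tumours where the anchor gene is amplified (GISTIC code 2, or
#' code >= 1 with `gain_counts = TRUE`), the fraction in which each
#' partner gene is also amplified — the signature of a shared amplicon.
#'
#' @param anchor Anchor gene symbol.
#' @param partners Character vector / `gene_set` of partner symbols.
#' @param calls Integer matrix of GISTIC codes (tumour x gene).
#' @param gain_counts Count gains (code >= 1) as amplified instead of
#'   strict amplification (code == 2).
#' @return data.frame per partner: `n_anchor_amplified`, `n_both`,
#'   `fraction`.
#' @export
coamplification <- function(anchor, partners, calls, gain_counts = FALSE) {
  thr <- if (gain_counts) 1L else 2L
  if (!anchor %in% colnames(calls)) {
    stop("anchor gene ", anchor, " absent from calls", call. = FALSE)
  }
  amp <- !is.na(calls[, anchor]) & calls[, anchor] >= thr
  n_anchor <- sum(amp)
  if (n_anchor == 0L) {
    stop("no tumours with amplified anchor: co-amplification fraction ",
         "undefined", call. = FALSE)
  }
  partners <- intersect(as.character(partners), colnames(calls))
  n_both <- vapply(partners, function(p) {
    sum(amp & !is.na(calls[, p]) & calls[, p] >= thr)
  }, integer(1))
  data.frame(partner = partners, n_anchor_amplified = n_anchor,
             n_both = unname(n_both),
             fraction = unname(n_both) / n_anchor,
             row.names = NULL, stringsAsFactors = FALSE)
}

#' Two-group comparison stratified by amplification status
#'
#' Mann-Whitney U comparison of a per-sample quantity (e.g. gene-effect
#' score or drug response) between amplified and non-amplified samples.
#'
#' @param values Named numeric vector (sample id -> value).
#' @param amplified Named logical vector (sample id -> amplified flag).
#' @param mode Passed to [mann_whitney()].
#' @return List with group sizes and medians plus the `vp_test`.
#' @export
stratify_by_amplification <- function(values, amplified,
                                      mode = c("auto", "exact", "normal")) {
  mode <- match.arg(mode)
  common <- intersect(names(values)[!is.na(values)],
                      names(amplified)[!is.na(amplified)])
  a <- values[common[amplified[common]]]
  b <- values[common[!amplified[common]]]
  if (length(a) < 2L || length(b) < 2L) {
    stop("insufficient group: need >= 2 amplified and >= 2 non-amplified ",
         sprintf("samples (got %d/%d)", length(a), length(b)),
         call. = FALSE)
  }
  test <- mann_whitney(a, b, mode = mode)
  list(n_amplified = length(a), n_other = length(b),
       median_amplified = stats::median(a), median_other = stats::median(b),
       test = test)
}

#' Kaplan-Meier curves and log-rank comparison across strata
#'
#' Wraps `survival::survfit` / `survival::survdiff` over a stratum
#' labelling of the cohort.
#'
#' @param os_months Non-negative follow-up times.
#' @param os_event Logical event indicators (`TRUE` = death observed).
#' @param strata Character/factor stratum labels, same length.
#' @return List with `chisq`, `df`, `p_value`, `medians` (per-stratum
#'   median survival), and the `survfit` object (`fit`).
#' @export
km_logrank <- function(os_months, os_event, strata) {
  keep <- !is.na(os_months) & !is.na(os_event) & !is.na(strata)
  os_months <- os_months[keep]; os_event <- as.logical(os_event[keep])
  strata <- factor(as.character(strata[keep]))
  if (nlevels(strata) < 2L) stop("need >= 2 strata", call. = FALSE)
  if (any(table(strata) == 0L)) stop("stratum with zero subjects",
                                     call. = FALSE)
  if (any(os_months < 0)) stop("negative survival times", call. = FALSE)
  ev_by <- tapply(os_event, strata, sum)
  if (any(ev_by == 0L)) {
    warning("stratum with zero events: ",
            paste(names(ev_by)[ev_by == 0L], collapse = ", "))
  }
  surv <- survival::Surv(os_months, os_event)
  sd <- survival::survdiff(surv ~ strata)
  df <- length(sd$n) - 1L
  p <- stats::pchisq(sd$chisq, df, lower.tail = FALSE)
  fit <- survival::survfit(surv ~ strata)
  med <- summary(fit)$table
  medians <- if (is.matrix(med)) med[, "median"] else med[["median"]]
  list(chisq = unname(sd$chisq), df = df, p_value = unname(p),
       medians = medians, fit = fit)
}
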