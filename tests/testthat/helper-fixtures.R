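# Shared fixture builders and independent brute-force oracles. Oracles are
# deliberately naive (per-gene loops, explicit set algebra) and share no
# code with the implementation they check.

toy_matrix <- function(values, lines, genes, role) {
  m <- matrix(values, nrow = length(lines), byrow = TRUE,
              dimnames = list(lines, genes))
  screen_matrix(m, role)
}

random_screen_pair <- function(n_lines, n_genes, na_frac = 0.05) {
  lines <- sprintf("L%02d", seq_len(n_lines))
  genes <- sprintf("g%02d", seq_len(n_genes))
  eff <- matrix(stats::rnorm(n_lines * n_genes, -0.3, 0.4),
                n_lines, n_genes, dimnames = list(lines, genes))
  prob <- matrix(stats::runif(n_lines * n_genes), n_lines, n_genes,
                 dimnames = list(lines, genes))
  miss <- stats::runif(n_lines * n_genes) < na_frac
  eff[miss] <- NA
  prob[miss] <- NA
  list(effect = screen_matrix(eff, "effect"),
       probability = screen_matrix(prob, "probability"))
}

# naive per-gene essentiality summary: explicit loops, no vectorization
oracle_summary <- function(eff, prob, threshold = 0.5) {
  genes <- colnames(prob)
  out <- NULL
  for (g in genes) {
    p <- unclass(prob)[, g]
    e <- unclass(eff)[, g]
    ess <- which(!is.na(p) & p >= threshold)
    n_scr <- sum(!is.na(p))
    med_dep <- if (length(ess)) stats::median(e[ess], na.rm = TRUE) else NA_real_
    out <- rbind(out, data.frame(
      symbol = g, n_essential = length(ess), n_screened = n_scr,
      frac_essential = length(ess) / n_scr,
      median_effect_dependent = med_dep,
      median_effect_all = stats::median(e, na.rm = TRUE),
      stringsAsFactors = FALSE))
  }
  rownames(out) <- NULL
  out
}

# independent filter chain: plain set operations over the summary rows
oracle_waterfall <- function(summ, druggable, common_essential,
                             core_fitness, min_frac = 0.09) {
  keep <- summ$symbol[summ$n_essential >= 1]
  keep <- keep[keep %in% druggable]
  keep <- keep[!(keep %in% c(common_essential, core_fitness))]
  frac <- summ$frac_essential[match(keep, summ$symbol)]
  keep[frac >= min_frac]
}

# fixed-sized summary table whose stage counts are fully controlled:
# n_total genes, all essential in >= 1 line; `excluded` symbols belong to
# the exclusion union; `low_freq` symbols sit below the frequency cutoff
synthetic_summary <- function(symbols, frac, n_screened = 100L) {
  data.frame(symbol = symbols,
             n_essential = as.integer(round(frac * n_screened)),
             n_screened = n_screened,
             frac_essential = frac,
             median_effect_dependent = -seq_along(symbols) / 100,
             median_effect_all = -seq_along(symbols) / 200,
             stringsAsFactors = FALSE)
}

write_lines_tmp <- function(lines) {
  f <- tempfile(fileext = ".txt")
  writeLines(lines, f)
  f
}

small_cfg <- function(seed = 1L, ...) {
  panel_config(n_lines = 40, n_genes = 200, n_primary = 30,
               n_druggable = 60, n_common_essential = 20,
               n_core_fitness = 15, exclusion_overlap = 10,
               n_druggable_excluded = 10, n_planted_targets = 5,
               n_lowfreq_targets = 5, seed = seed, ...)
}
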