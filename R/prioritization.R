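# The filtration waterfall: essentiality calls from dependency
# probabilities, per-gene summaries, the four-stage druggable-target
# filter with a conservation-checked audit, release comparison, and the
# plot-ready scatter table.

#' Call per-(line, gene) essentiality from dependency probabilities
#'
#' A gene is called essential in a cell line when its dependency
#' probability is at least `threshold` (inclusive, 0.5 by default — the
#' conventional cutoff for membership in the essential score
#' distribution). Missing probabilities are not essential and do not count
#' toward the gene's screened-line denominator.
#'
#' @param prob A `screen_matrix` with role `"probability"`.
#' @param threshold Probability cutoff in (0, 1\].
#' @return An `essentiality_call`: list with logical matrix `essential`
#'   (line x gene) and integer vector `screened_n` (non-missing lines per
#'   gene).
#' @export
call_essential <- function(prob, threshold = 0.5) {
  stopifnot(inherits(prob, "screen_matrix"))
  if (matrix_role(prob) != "probability") {
    stop("call_essential() needs a probability matrix, got role ",
         sQuote(matrix_role(prob)), call. = FALSE)
  }
  if (!is.numeric(threshold) || length(threshold) != 1L ||
      threshold <= 0 || threshold > 1) {
    stop("threshold must lie in (0, 1]", call. = FALSE)
  }
  vals <- unclass(prob)
  ess <- !is.na(vals) & vals >= threshold
  structure(list(essential = ess,
                 screened_n = colSums(!is.na(vals)),
                 threshold = threshold),
            class = "essentiality_call")
}

#' Summarize essentiality per gene
#'
#' For each gene: the number and fraction of cell lines where it is called
#' essential, the median gene-effect score over those dependent lines (the
#' y-axis of the prioritization scatter plot; `NA` when no line is
#' dependent), and the median over all screened lines.
#'
#' @param effect A `screen_matrix` with role `"effect"`.
#' @param calls An `essentiality_call` from [call_essential()].
#' @return data.frame, one row per gene: `symbol`, `n_essential`,
#'   `n_screened`, `frac_essential`, `median_effect_dependent`,
#'   `median_effect_all`.
#' @export
summarize_essentiality <- function(effect, calls) {
  stopifnot(inherits(effect, "screen_matrix"),
            inherits(calls, "essentiality_call"))
  if (matrix_role(effect) != "effect") {
    stop("summarize_essentiality() needs an effect matrix", call. = FALSE)
  }
  ess <- calls$essential
  # genes only in the effect matrix are dropped with a warning (releases
  # differ slightly in gene universes); any other mismatch is an error
  only_eff <- setdiff(colnames(effect), colnames(ess))
  if (length(only_eff)) {
    warning("dropping ", length(only_eff),
            " gene(s) absent from the probability matrix: ",
            paste(utils::head(only_eff, 5), collapse = ", "),
            if (length(only_eff) > 5) ", ..." else "")
    effect <- screen_matrix(unclass(effect)[, setdiff(colnames(effect),
                                                      only_eff),
                                            drop = FALSE], "effect")
  }
  sym_diff <- c(setdiff(colnames(ess), colnames(effect)),
                setdiff(rownames(ess), rownames(effect)),
                setdiff(rownames(effect), rownames(ess)))
  if (length(sym_diff)) {
    stop("effect and probability universes differ: ",
         paste(utils::head(sym_diff, 10), collapse = ", "), call. = FALSE)
  }
  genes <- colnames(ess)
  lines <- rownames(ess)
  eff <- unclass(effect)[lines, genes, drop = FALSE]
  n_ess <- colSums(ess)
  med_dep <- vapply(seq_along(genes), function(j) {
    dep <- eff[ess[, j], j]
    if (!length(dep)) NA_real_ else stats::median(dep, na.rm = TRUE)
  }, numeric(1))
  med_all <- apply(eff, 2, stats::median, na.rm = TRUE)
  data.frame(symbol = genes,
             n_essential = as.integer(n_ess),
             n_screened = as.integer(calls$screened_n[genes]),
             frac_essential = as.numeric(n_ess / calls$screened_n[genes]),
             median_effect_dependent = med_dep,
             median_effect_all = as.numeric(med_all),
             row.names = NULL, stringsAsFactors = FALSE)
}

#' Run the target-prioritization waterfall
#'
#' Four filter stages over a per-gene essentiality summary:
#' \enumerate{
#'   \item keep genes essential in at least one cell line;
#'   \item intersect with the druggable-gene set;
#'   \item remove the union of common-essential and core-fitness genes
#'     (dependencies shared with normal tissue — no therapeutic window);
#'   \item remove genes essential in fewer than `min_frac` of the panel
#'     (small-n calls dominated by stochastic effects).
#' }
#' The survivors are ranked by essentiality frequency (descending), then
#' by median dependent-line gene effect (ascending: more negative = a
#' stronger dependency first), then by symbol. Every stage is recorded in
#' a conservation-checked audit (`n_in = n_out + removed` at each stage).
#'
#' @param summary Per-gene data.frame from [summarize_essentiality()].
#' @param druggable,common_essential,core_fitness `gene_set` objects (the
#'   exclusion sets may be empty via `allow_empty`).
#' @param min_frac Minimum essentiality fraction (default 0.09, i.e. the
#'   gene must be essential in at least 9% of the panel).
#' @param rank_by Median used for the secondary sort key:
#'   `"dependent"` (default) or `"all"` lines.
#' @return List with `ranked` (summary rows plus `rank`) and `audit`
#'   (a `prioritization_audit`).
#' @export
run_waterfall <- function(summary, druggable, common_essential,
                          core_fitness, min_frac = 0.09,
                          rank_by = c("dependent", "all")) {
  rank_by <- match.arg(rank_by)
  stopifnot(is.data.frame(summary))
  if (!length(druggable)) {
    stop("druggable gene set is empty", call. = FALSE)
  }
  if (!is.numeric(min_frac) || min_frac < 0 || min_frac > 1) {
    stop("min_frac must lie in [0, 1]", call. = FALSE)
  }

  stages <- list()
  record <- function(name, before, after, params = list()) {
    removed <- setdiff(before$symbol, after$symbol)
    stages[[length(stages) + 1L]] <<- list(
      stage_name = name, n_in = nrow(before), n_out = nrow(after),
      removed = removed, parameters = params)
    after
  }

  cur <- summary
  s1 <- cur[cur$n_essential >= 1L, , drop = FALSE]
  cur <- record("essential_in_any_line", cur, s1)
  s2 <- cur[cur$symbol %in% as.character(druggable), , drop = FALSE]
  cur <- record("druggable", cur, s2)
  excl <- union(as.character(common_essential), as.character(core_fitness))
  s3 <- cur[!(cur$symbol %in% excl), , drop = FALSE]
  cur <- record("not_common_essential_or_core_fitness", cur, s3,
                params = list(n_common_essential = length(common_essential),
                              n_core_fitness = length(core_fitness),
                              n_union = length(excl)))
  s4 <- cur[cur$frac_essential >= min_frac, , drop = FALSE]
  cur <- record("frequency_at_least_min_frac", cur, s4,
                params = list(min_frac = min_frac))

  key <- if (rank_by == "dependent") cur$median_effect_dependent
         else cur$median_effect_all
  ord <- order(-cur$n_essential, key, cur$symbol)
  ranked <- cur[ord, , drop = FALSE]
  ranked$rank <- seq_len(nrow(ranked))
  rownames(ranked) <- NULL

  audit <- structure(list(stages = stages,
                          parameters = list(min_frac = min_frac,
                                            rank_by = rank_by)),
                     class = "prioritization_audit")
  validate_audit(audit)
  list(ranked = ranked, audit = audit)
}

validate_audit <- function(audit) {
  st <- audit$stages
  for (i in seq_along(st)) {
    s <- st[[i]]
    if (s$n_in - s$n_out != length(s$removed)) {
      stop("audit conservation violated at stage ", s$stage_name,
           call. = FALSE)
    }
    if (i > 1L && st[[i - 1L]]$n_out != s$n_in) {
      stop("audit stage chaining violated at stage ", s$stage_name,
           call. = FALSE)
    }
  }
  invisible(audit)
}

#' Audit waterfall as a stage-count table
#' @param audit A `prioritization_audit`.
#' @return data.frame with `stage`, `n_in`, `n_out`, `n_removed`.
#' @export
audit_table <- function(audit) {
  stopifnot(inherits(audit, "prioritization_audit"))
  do.call(rbind, lapply(audit$stages, function(s) {
    data.frame(stage = s$stage_name, n_in = s$n_in, n_out = s$n_out,
               n_removed = length(s$removed), stringsAsFactors = FALSE)
  }))
}

#' @export
print.prioritization_audit <- function(x, ...) {
  print(audit_table(x))
  invisible(x)
}

#' Compare two prioritized releases
#'
#' @param list_a,list_b `gene_set`s (or character vectors of symbols),
#'   e.g. the prioritized lists from two data releases.
#' @return List of counts `common`, `added`, `removed` and the membership
#'   vectors. `common + added = |B|`, `common + removed = |A|`.
#' @export
compare_releases <- function(list_a, list_b) {
  a <- unique(as.character(list_a)); b <- unique(as.character(list_b))
  list(common = length(intersect(a, b)),
       added = length(setdiff(b, a)),
       removed = length(setdiff(a, b)),
       common_genes = intersect(a, b),
       added_genes = setdiff(b, a),
       removed_genes = setdiff(a, b))
}

#' Plot-ready scatter table for the prioritization landscape
#'
#' One row per ranked gene with the scatter-plot axes (percent of lines
#' where the gene is essential; median gene effect) plus overlay flags for
#' the exclusion sets and the low-frequency region.
#'
#' @param ranked Ranked data.frame from [run_waterfall()] (or any
#'   essentiality summary with the same columns).
#' @param common_essential,core_fitness Optional `gene_set`s for the
#'   overlay flags.
#' @param min_frac Low-frequency overlay threshold (default 0.09).
#' @return data.frame in rank order: `symbol`, `pct_essential`,
#'   `median_effect_dependent`, `median_effect_all`, `is_common_essential`,
#'   `is_core_fitness`, `is_low_frequency`.
#' @export
scatter_table <- function(ranked, common_essential = character(0),
                          core_fitness = character(0), min_frac = 0.09) {
  cols <- c("symbol", "pct_essential", "median_effect_dependent",
            "median_effect_all", "is_common_essential", "is_core_fitness",
            "is_low_frequency")
  if (!nrow(ranked)) {
    out <- data.frame(symbol = character(0), pct_essential = numeric(0),
                      median_effect_dependent = numeric(0),
                      median_effect_all = numeric(0),
                      is_common_essential = logical(0),
                      is_core_fitness = logical(0),
                      is_low_frequency = logical(0))
    return(out[, cols])
  }
  data.frame(symbol = ranked$symbol,
             pct_essential = 100 * ranked$frac_essential,
             median_effect_dependent = ranked$median_effect_dependent,
             median_effect_all = ranked$median_effect_all,
             is_common_essential = ranked$symbol %in%
               as.character(common_essential),
             is_core_fitness = ranked$symbol %in% as.character(core_fitness),
             is_low_frequency = ranked$frac_essential < min_frac,
             stringsAsFactors = FALSE)[, cols]
}

#' Triage targets with clinical-stage inhibitors for repurposing
#'
#' Given a per-target clinical-inhibitor table (exported from an external
#' drug-knowledge resource), counts the targets whose most advanced
#' inhibitor has reached at least phase II and splits them into those
#' already in trials for the cancer type of interest vs. those positioned
#' for near-term repurposing.
#'
#' @param clinical data.frame with columns `symbol`, `max_phase` (integer,
#'   0 = preclinical .. 4 = approved) and `in_disease_trial` (logical:
#'   already trialled for the cancer type under study).
#' @param min_phase Minimum development phase (default 2).
#' @return List with counts `n_clinical`, `n_in_disease_trials`,
#'   `n_repurposable` and the corresponding symbol vectors.
#' @export
triage_clinical <- function(clinical, min_phase = 2L) {
  need <- c("symbol", "max_phase", "in_disease_trial")
  miss <- setdiff(need, names(clinical))
  if (length(miss)) {
    stop("clinical table missing columns: ", paste(miss, collapse = ", "),
         call. = FALSE)
  }
  clin <- clinical[!is.na(clinical$max_phase) &
                     clinical$max_phase >= min_phase, , drop = FALSE]
  in_trial <- clin$symbol[clin$in_disease_trial %in% TRUE]
  repur <- setdiff(clin$symbol, in_trial)
  list(n_clinical = nrow(clin),
       n_in_disease_trials = length(in_trial),
       n_repurposable = length(repur),
       clinical_targets = clin$symbol,
       in_disease_trials = in_trial,
       repurposable = repur)
}
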