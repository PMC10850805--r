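# Validation of prioritized targets with drug-response data: cell lines
# are stratified into dependency quartiles on the gene-effect score and
# high- vs low-dependency responses to inhibitors of the target are
# compared (Welch ANOVA with Dunnett correction against the low stratum).

#' Stratify cell lines into dependency quartiles
#'
#' Splits lines into high dependency (top quartile = most negative
#' gene-effect scores), intermediate (middle half) and low (bottom
#' quartile). Quartile boundaries use linear interpolation on the sorted
#' values (position `p * (n - 1)`, i.e. `stats::quantile` type 7);
#' boundary membership is inclusive on both tails.
#'
#' @param effect_vector Named numeric vector (line id -> gene-effect
#'   score); at least 4 non-missing values.
#' @return A `dependency_strata`: list with `assignment` (named character
#'   vector in `high`/`intermediate`/`low`), `q1`, `q3`.
#' @export
stratify_by_dependency <- function(effect_vector) {
  v <- effect_vector[!is.na(effect_vector)]
  if (length(v) < 4L) {
    stop("need >= 4 non-missing gene-effect values to form quartiles",
         call. = FALSE)
  }
  if (length(unique(v)) == 1L) {
    stop("degenerate gene-effect distribution: all values identical",
         call. = FALSE)
  }
  if (is.null(names(v))) names(v) <- seq_along(v)
  q <- stats::quantile(v, c(0.25, 0.75), type = 7, names = FALSE)
  assignment <- ifelse(v <= q[1], "high",
                       ifelse(v >= q[2], "low", "intermediate"))
  structure(list(assignment = assignment, q1 = q[1], q3 = q[2]),
            class = "dependency_strata")
}

#' @export
print.dependency_strata <- function(x, ...) {
  tab <- table(factor(x$assignment, c("high", "intermediate", "low")))
  cat(sprintf("<dependency_strata> high %d / intermediate %d / low %d (q1 = %.3g, q3 = %.3g)\n",
              tab["high"], tab["intermediate"], tab["low"], x$q1, x$q3))
  invisible(x)
}

#' Compare drug responses across dependency strata
#'
#' Joins responses to strata on line id, drops strata left with fewer than
#' 2 values (warning), then runs a Welch one-way ANOVA across the
#' remaining strata with Dunnett-adjusted pairwise comparisons against the
#' low-dependency stratum as control. With only two strata the omnibus
#' falls back to a Welch t-test (or Mann-Whitney via `fallback`). Both
#' response metrics are oriented so lower = stronger response, so a
#' validated target has a *lower* mean response in the high stratum.
#'
#' @param strata A `dependency_strata`.
#' @param responses data.frame with `line_id` and `value` columns (one
#'   response per line, e.g. ln IC50 or AUC for one drug).
#' @param alpha Significance level for the validation flag.
#' @param fallback Two-group test when only 2 strata survive: `"welch_t"`
#'   or `"mann_whitney"`.
#' @param mc_draws,mc_seed Passed to [dunnett_adjust()].
#' @return A `validation_result`: list with per-stratum `n` and `means`,
#'   `omnibus` (a `vp_test`), `pairwise` (Dunnett vs low, `NULL` when the
#'   fallback ran), `p_high_vs_low` (adjusted when available),
#'   `direction` (sign of high-minus-low mean response), `validated`.
#' @export
compare_response <- function(strata, responses, alpha = 0.05,
                             fallback = c("welch_t", "mann_whitney"),
                             mc_draws = 1e5, mc_seed = NULL) {
  fallback <- match.arg(fallback)
  stopifnot(inherits(strata, "dependency_strata"))
  resp <- responses[!is.na(responses$value), , drop = FALSE]
  common <- intersect(names(strata$assignment), as.character(resp$line_id))
  if (!length(common)) {
    stop("no overlapping line ids between strata and responses",
         call. = FALSE)
  }
  resp <- resp[resp$line_id %in% common, , drop = FALSE]
  lab <- strata$assignment[as.character(resp$line_id)]
  groups <- split(resp$value, factor(lab, c("high", "intermediate", "low")))
  small <- names(groups)[lengths(groups) > 0L & lengths(groups) < 2L]
  if (length(small)) {
    warning("dropping strata with < 2 responses: ",
            paste(small, collapse = ", "))
  }
  groups <- groups[lengths(groups) >= 2L]
  if (length(groups) < 2L) {
    stop("need >= 2 strata with >= 2 responses each", call. = FALSE)
  }
  means <- vapply(groups, mean, numeric(1))
  ns <- lengths(groups)

  pairwise <- NULL
  if (length(groups) >= 3L) {
    omnibus <- welch_anova(groups)
    ctrl <- which(names(groups) == "low")
    pairwise <- dunnett_adjust(groups, control_index = ctrl,
                               mc_draws = mc_draws, mc_seed = mc_seed)
    p_hl <- unname(pairwise$adjusted["high"])
  } else {
    omnibus <- if (fallback == "welch_t") {
      welch_t(groups[[1]], groups[[2]])
    } else {
      mann_whitney(groups[[1]], groups[[2]])
    }
    p_hl <- if (all(c("high", "low") %in% names(groups)))
      omnibus$p_value else NA_real_
  }
  direction <- if (all(c("high", "low") %in% names(groups)))
    sign(means["high"] - means["low"]) else NA_real_
  validated <- isTRUE(!is.na(p_hl) && p_hl < alpha && direction < 0)
  structure(list(n = ns, means = means, omnibus = omnibus,
                 pairwise = pairwise, p_high_vs_low = p_hl,
                 direction = unname(direction), validated = validated,
                 n_joined = nrow(resp), n_strata_used = length(groups)),
            class = "validation_result")
}

#' @export
print.validation_result <- function(x, ...) {
  cat(sprintf("<validation_result> %s; p(high vs low) = %.3g; %svalidated\n",
              x$omnibus$method, x$p_high_vs_low,
              if (x$validated) "" else "not "))
  invisible(x)
}

#' Group dose-response curves by dependency stratum
#'
#' Averages per-concentration viability across the high- and
#' low-dependency strata. Curves whose concentration grids differ are
#' linearly interpolated onto the union grid (restricted to each curve's
#' observed range); when that happens `interpolated = TRUE` is flagged.
#' The separation score is the mean over concentrations of
#' (mean high viability - mean low viability): negative when
#' high-dependency lines are killed more effectively.
#'
#' @param curves data.frame with `line_id`, `concentration`, `viability`.
#' @param strata A `dependency_strata`.
#' @return List with `table` (per-concentration mean and SD viability per
#'   stratum), `separation_score`, `interpolated`, and per-stratum curve
#'   counts.
#' @export
dose_curve_groups <- function(curves, strata) {
  stopifnot(inherits(strata, "dependency_strata"))
  curves$line_id <- as.character(curves$line_id)
  lab <- strata$assignment[curves$line_id]
  curves <- curves[!is.na(lab) & lab %in% c("high", "low"), , drop = FALSE]
  lab <- strata$assignment[curves$line_id]
  for (s in c("high", "low")) {
    if (!any(lab == s)) stop("empty stratum: ", s, call. = FALSE)
  }
  by_line <- split(curves, curves$line_id)
  grids <- lapply(by_line, function(d) sort(d$concentration))
  if (any(vapply(grids, function(g) any(diff(g) <= 0), logical(1)))) {
    stop("dose concentrations must be strictly increasing per curve",
         call. = FALSE)
  }
  grid <- sort(unique(curves$concentration))
  interpolated <- !all(vapply(grids, function(g) identical(g, grid),
                              logical(1)))
  per_line <- lapply(by_line, function(d) {
    d <- d[order(d$concentration), ]
    v <- stats::approx(d$concentration, d$viability, xout = grid,
                       rule = 1)$y
    v
  })
  mat <- do.call(rbind, per_line)  # line x concentration
  stratum <- strata$assignment[rownames(mat)]
  summarize <- function(s) {
    m <- mat[stratum == s, , drop = FALSE]
    data.frame(stratum = s, concentration = grid,
               mean_viability = colMeans(m, na.rm = TRUE),
               sd_viability = apply(m, 2, stats::sd, na.rm = TRUE),
               n = colSums(!is.na(m)), stringsAsFactors = FALSE)
  }
  tab <- rbind(summarize("high"), summarize("low"))
  hi <- tab$mean_viability[tab$stratum == "high"]
  lo <- tab$mean_viability[tab$stratum == "low"]
  sep <- mean(hi - lo, na.rm = TRUE)
  list(table = tab, separation_score = sep, interpolated = interpolated,
       n_high = sum(stratum == "high"), n_low = sum(stratum == "low"))
}

#' Validate a set of targets against a drug-response table
#'
#' Convenience driver: for each (target, drug) pair whose drug annotates
#' the target, stratifies lines on the target's gene-effect column and
#' runs [compare_response()]. Lines with drug data but no CRISPR data (or
#' vice versa) are dropped pair-wise, with the joined n recorded.
#'
#' @param effect A `screen_matrix` with role `"effect"`.
#' @param drug_response Long-format data.frame from
#'   [read_drug_response()].
#' @param targets `gene_set` (or character vector) of target symbols.
#' @param metric `"ln_ic50"` (default) or `"auc"`.
#' @param ... Passed to [compare_response()].
#' @return data.frame, one row per (target, drug): stratum sizes, means,
#'   p-values, direction, `validated`.
#' @export
validate_targets <- function(effect, drug_response, targets,
                             metric = c("ln_ic50", "auc"), ...) {
  metric <- match.arg(metric)
  stopifnot(inherits(effect, "screen_matrix"))
  dr <- drug_response[drug_response$metric == metric, , drop = FALSE]
  rows <- list()
  for (target in intersect(as.character(targets), colnames(effect))) {
    hits <- vapply(strsplit(as.character(dr$target_genes), ";"),
                   function(g) target %in% trimws(g), logical(1))
    drt <- dr[hits, , drop = FALSE]
    if (!nrow(drt)) next
    ev <- unclass(effect)[, target]
    strata <- tryCatch(stratify_by_dependency(ev), error = function(e) NULL)
    if (is.null(strata)) next
    for (drug in unique(drt$drug_id)) {
      d <- drt[drt$drug_id == drug, c("line_id", "value")]
      d <- d[!duplicated(d$line_id), , drop = FALSE]
      res <- tryCatch(compare_response(strata, d, ...),
                      error = function(e) NULL)
      if (is.null(res)) next
      rows[[length(rows) + 1L]] <- data.frame(
        target = target, drug_id = drug,
        n_joined = res$n_joined,
        n_high = if ("high" %in% names(res$n)) res$n[["high"]] else 0L,
        n_low = if ("low" %in% names(res$n)) res$n[["low"]] else 0L,
        mean_high = if ("high" %in% names(res$means)) res$means[["high"]] else NA_real_,
        mean_low = if ("low" %in% names(res$means)) res$means[["low"]] else NA_real_,
        omnibus_p = res$omnibus$p_value,
        p_high_vs_low = res$p_high_vs_low,
        direction = res$direction,
        validated = res$validated, stringsAsFactors = FALSE)
    }
  }
  if (!length(rows)) {
    return(data.frame(target = character(0), drug_id = character(0),
                      n_joined = integer(0), n_high = integer(0),
                      n_low = integer(0), mean_high = numeric(0),
                      mean_low = numeric(0), omnibus_p = numeric(0),
                      p_high_vs_low = numeric(0), direction = numeric(0),
                      validated = logical(0)))
  }
  out <- do.call(rbind, rows)
  rownames(out) <- NULL
  out
}
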