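# Seeded generator for a complete synthetic study: screen matrices,
# annotations, mutations, expression, copy number, drug responses and a
# tumour cohort, with planted ground truth for every pipeline stage.
#
# Gene-class labels (and hence the planted truth) are a pure function of
# the configuration; randomness only enters the drawn values. Each output
# gets its own RNG stream derived from the master seed, so adding a new
# output never perturbs existing ones.

# stable per-component sub-seed, kept inside 32-bit integer range
stream_seed <- function(seed, index) {
  (as.numeric(seed) * 48271 + index * 9973) %% 2147483647
}

with_stream <- function(seed, index, expr) {
  old <- if (exists(".Random.seed", globalenv()))
    get(".Random.seed", globalenv()) else NULL
  on.exit({
    if (is.null(old)) suppressWarnings(rm(".Random.seed", envir = globalenv()))
    else assign(".Random.seed", old, globalenv())
  })
  set.seed(stream_seed(seed, index))
  force(expr)
}

#' Configuration for the synthetic screen panel
#'
#' Defaults mirror a realistic squamous-carcinoma study: an 87-line panel
#' (a 63-line HPV-negative primary-lineage panel extended with 24 lines
#' of a closely related lineage), 2000 screened genes, 20 planted
#' cancer-type-specific targets dependent in 30% of lines, five mutation
#' biomarkers at >= 5% prevalence, one six-gene amplicon, and a 523-tumour
#' cohort (415 HPV-negative / 72 positive / 36 unknown).
#'
#' Gene-effect scores follow the Chronos scaling convention: non-essential
#' genes centre at 0 (SD 0.15), common-essential and core-fitness genes at
#' -1 (SD 0.2) in every line, planted targets at -0.6 (SD 0.15) in their
#' dependent lines. Dependency probabilities are drawn directly —
#' Uniform(0.6, 1) for dependent (line, gene) cells, Uniform(0, 0.4)
#' otherwise — so filter behaviour is exactly predictable.
#'
#' @param n_lines,n_genes Panel dimensions.
#' @param n_primary Lines in the primary lineage (rest = related lineage).
#' @param n_druggable,n_common_essential,n_core_fitness,exclusion_overlap
#'   Gene-class sizes; `exclusion_overlap` genes belong to both exclusion
#'   sets.
#' @param n_planted_targets Druggable, cancer-type-specific dependencies.
#' @param planted_dependent_fraction Fraction of lines dependent on each
#'   planted target.
#' @param n_druggable_excluded How many exclusion-set genes are also
#'   druggable (real druggable lists overlap the common-essential and
#'   core-fitness sets, which is what the third filter stage removes).
#' @param n_lowfreq_targets,lowfreq_dependent_fraction Druggable genes
#'   dependent in only a small fraction of lines (default 5% < the 9%
#'   cutoff) — the population the frequency filter removes.
#' @param effect_params List of `mean`/`sd` per gene class.
#' @param biomarkers Named numeric vector of mutation prevalences.
#' @param planted_associations data.frame(`target_index`, `biomarker`,
#'   `shift`) — shift of the indexed planted target's effect in
#'   biomarker-mutant lines, in baseline-SD units.
#' @param amplicon List: `anchor_index` (which planted target anchors the
#'   amplicon), `n_partners`, `amplified_fraction`, plus tumour-cohort
#'   rates `tumour_gain_rate`, `tumour_amp_rate`, `partner_coamp_rate`.
#' @param planted_drugs data.frame(`drug_id`, `target_index`, `slope`) —
#'   ln IC50 responds to the target's effect score with this slope.
#' @param expression_rho Planted correlation between the anchor target's
#'   expression and its dependency (negative: low expression, strong
#'   dependency).
#' @param n_tumours,n_hpv_positive,n_hpv_unknown Tumour-cohort layout.
#' @param survival_rates Exponential hazard (per month) by amplification
#'   stratum, `c(amplified = ..., other = ...)`; equal by default.
#' @param drug_line_fraction Fraction of lines with drug-response data.
#' @param seed Master seed.
#' @return A `panel_config` list.
#' @export
panel_config <- function(n_lines = 87, n_genes = 2000, n_primary = 63,
                         n_druggable = 200, n_common_essential = 80,
                         n_core_fitness = 60, exclusion_overlap = 40,
                         n_planted_targets = 20,
                         planted_dependent_fraction = 0.3,
                         n_druggable_excluded = 30,
                         n_lowfreq_targets = 15,
                         lowfreq_dependent_fraction = 0.05,
                         effect_params = list(
                           nonessential = c(mean = 0, sd = 0.15),
                           excluded = c(mean = -1, sd = 0.2),
                           planted = c(mean = -0.6, sd = 0.15)),
                         biomarkers = c(BM1 = 0.79, BM2 = 0.30, BM3 = 0.25,
                                        BM4 = 0.18, BM5 = 0.15),
                         planted_associations = data.frame(
                           target_index = integer(0),
                           biomarker = character(0), shift = numeric(0)),
                         amplicon = list(anchor_index = 1L, n_partners = 5L,
                                         amplified_fraction = 0.21,
                                         tumour_gain_rate = 0.70,
                                         tumour_amp_rate = 0.123,
                                         partner_coamp_rate = 0.95),
                         planted_drugs = data.frame(
                           drug_id = "DRUG1", target_index = 1L, slope = 2),
                         expression_rho = -0.6,
                         n_tumours = 523, n_hpv_positive = 72,
                         n_hpv_unknown = 36,
                         survival_rates = c(amplified = 0.02, other = 0.02),
                         drug_line_fraction = 0.6,
                         seed = 1L) {
  cfg <- as.list(environment())
  n_class <- n_common_essential + n_core_fitness - exclusion_overlap +
    n_planted_targets + n_lowfreq_targets
  if (n_class > n_genes) stop("gene class sizes exceed n_genes",
                              call. = FALSE)
  if (n_druggable < n_planted_targets + n_lowfreq_targets +
        n_druggable_excluded) {
    stop("druggable set too small for its planted sub-classes",
         call. = FALSE)
  }
  if (n_druggable_excluded > n_common_essential + n_core_fitness -
        exclusion_overlap) {
    stop("n_druggable_excluded exceeds the exclusion-set union",
         call. = FALSE)
  }
  if (n_primary > n_lines) stop("n_primary exceeds n_lines", call. = FALSE)
  stopifnot(planted_dependent_fraction > 0, planted_dependent_fraction < 1,
            amplicon$amplified_fraction > 0, amplicon$amplified_fraction < 1)
  structure(cfg, class = "panel_config")
}

# Deterministic class labelling: genes are G0001..G<n>; the exclusion sets
# occupy the front block (with their overlap), planted targets follow, and
# the rest of the druggable set comes after. Truth never touches the RNG.
panel_truth <- function(cfg) {
  genes <- sprintf("G%04d", seq_len(cfg$n_genes))
  ce <- genes[seq_len(cfg$n_common_essential)]
  cf_start <- cfg$n_common_essential - cfg$exclusion_overlap + 1L
  cf <- genes[seq(cf_start, length.out = cfg$n_core_fitness)]
  n_excl <- length(union(ce, cf))
  planted <- genes[seq(n_excl + 1L, length.out = cfg$n_planted_targets)]
  lowfreq <- genes[seq(n_excl + cfg$n_planted_targets + 1L,
                       length.out = cfg$n_lowfreq_targets)]
  n_extra <- cfg$n_druggable - cfg$n_planted_targets -
    cfg$n_lowfreq_targets - cfg$n_druggable_excluded
  extra_drug <- genes[seq(n_excl + cfg$n_planted_targets +
                            cfg$n_lowfreq_targets + 1L,
                          length.out = n_extra)]
  druggable <- c(planted, lowfreq,
                 union(ce, cf)[seq_len(cfg$n_druggable_excluded)],
                 extra_drug)
  anchor <- planted[cfg$amplicon$anchor_index]
  partners <- sprintf("AMP%d", seq_len(cfg$amplicon$n_partners))
  lines <- sprintf("LINE%03d", seq_len(cfg$n_lines))
  expected_survivors <- character(0)
  if (cfg$planted_dependent_fraction >= 0.09)
    expected_survivors <- c(expected_survivors, planted)
  if (cfg$lowfreq_dependent_fraction >= 0.09)
    expected_survivors <- c(expected_survivors, lowfreq)
  list(genes = genes, lines = lines,
       common_essential = ce, core_fitness = cf, druggable = druggable,
       planted_targets = planted, lowfreq_targets = lowfreq,
       anchor = anchor,
       amplicon_partners = partners,
       expected_waterfall_survivors = expected_survivors,
       planted_associations = if (nrow(cfg$planted_associations))
         data.frame(target = planted[cfg$planted_associations$target_index],
                    biomarker = cfg$planted_associations$biomarker,
                    shift = cfg$planted_associations$shift,
                    stringsAsFactors = FALSE)
       else data.frame(target = character(0), biomarker = character(0),
                       shift = numeric(0)),
       planted_drugs = data.frame(
         drug_id = cfg$planted_drugs$drug_id,
         target = planted[cfg$planted_drugs$target_index],
         slope = cfg$planted_drugs$slope, stringsAsFactors = FALSE))
}

#' Generate the synthetic panel bundle
#'
#' Draws every dataset of the study from the configuration, optionally
#' writing the full file bundle (panel IO schemas plus `truth.json`) to a
#' directory. Identical seeds give identical bundles.
#'
#' @param cfg A [panel_config()].
#' @param dir Optional output directory; created if needed.
#' @return List with the in-memory objects (`effect`, `probability`,
#'   `expression`, `copy_number` screen matrices; `annotation`,
#'   `mutations`, `drug_response`, `dose_curves`, `tumours` data.frames;
#'   gene sets; `truth`).
#' @export
generate_panel <- function(cfg, dir = NULL) {
  stopifnot(inherits(cfg, "panel_config"))
  truth <- panel_truth(cfg)
  genes <- truth$genes; lines <- truth$lines
  n_l <- cfg$n_lines; n_g <- cfg$n_genes
  excl <- union(truth$common_essential, truth$core_fitness)
  ep <- cfg$effect_params

  # dependent-line subsets per planted (and low-frequency) target (stream 1)
  dep_lines <- with_stream(cfg$seed, 1L, {
    n_dep <- round(cfg$planted_dependent_fraction * n_l)
    n_low <- round(cfg$lowfreq_dependent_fraction * n_l)
    c(stats::setNames(lapply(truth$planted_targets, function(g)
        sample(lines, n_dep)), truth$planted_targets),
      stats::setNames(lapply(truth$lowfreq_targets, function(g)
        sample(lines, n_low)), truth$lowfreq_targets))
  })
  # amplified lines (stream 2); the anchor's dependent lines are then
  # re-planted outside the amplified subset so amplification damps
  # dependency, as on a real passenger-amplified locus
  amp_lines <- with_stream(cfg$seed, 2L, {
    sample(lines, round(cfg$amplicon$amplified_fraction * n_l))
  })
  if (length(dep_lines)) {
    non_amp <- setdiff(lines, amp_lines)
    n_dep <- length(dep_lines[[1]])
    if (n_dep <= length(non_amp)) {
      dep_lines[[truth$anchor]] <- with_stream(cfg$seed, 3L,
                                               sample(non_amp, n_dep))
    }
  }

  dep_mask <- matrix(FALSE, n_l, n_g, dimnames = list(lines, genes))
  for (g in names(dep_lines)) dep_mask[dep_lines[[g]], g] <- TRUE
  dep_mask[, excl] <- TRUE

  # mutation status per biomarker (stream 4), before effects so planted
  # association shifts can enter the effect draw
  mut_status <- with_stream(cfg$seed, 4L, {
    vapply(cfg$biomarkers, function(prev) stats::runif(n_l) < prev,
           logical(n_l))
  })
  rownames(mut_status) <- lines

  effect_vals <- with_stream(cfg$seed, 5L, {
    m <- matrix(stats::rnorm(n_l * n_g, ep$nonessential["mean"],
                             ep$nonessential["sd"]),
                n_l, n_g, dimnames = list(lines, genes))
    m[, excl] <- stats::rnorm(n_l * length(excl), ep$excluded["mean"],
                              ep$excluded["sd"])
    for (g in c(truth$planted_targets, truth$lowfreq_targets)) {
      dl <- dep_lines[[g]]
      m[dl, g] <- stats::rnorm(length(dl), ep$planted["mean"],
                               ep$planted["sd"])
    }
    pa <- truth$planted_associations
    for (i in seq_len(nrow(pa))) {
      mut <- lines[mut_status[, pa$biomarker[i]]]
      m[mut, pa$target[i]] <- m[mut, pa$target[i]] +
        pa$shift[i] * ep$nonessential["sd"]
    }
    m
  })

  prob_vals <- with_stream(cfg$seed, 6L, {
    lo <- matrix(stats::runif(n_l * n_g, 0, 0.4), n_l, n_g,
                 dimnames = list(lines, genes))
    hi <- matrix(stats::runif(n_l * n_g, 0.6, 1), n_l, n_g)
    ifelse(dep_mask, hi, lo)
  })

  # expression: log2(TPM+1) baseline Normal(4, 1); the anchor gets the
  # planted dependency correlation via the usual Gaussian construction
  expr_vals <- with_stream(cfg$seed, 7L, {
    m <- matrix(stats::rnorm(n_l * n_g, 4, 1), n_l, n_g,
                dimnames = list(lines, genes))
    rho <- cfg$expression_rho
    z_eff <- as.numeric(scale(effect_vals[, truth$anchor]))
    # rho is between expression and *dependency strength*; dependency is
    # strong when effect is negative, so correlate with -effect
    m[, truth$anchor] <- 4 + (rho * (-z_eff) +
                                sqrt(1 - rho^2) * stats::rnorm(n_l))
    pmax(m, 0)
  })

  # cell-line copy number (log2 ratio); amplicon block elevated in the
  # amplified lines
  cn_vals <- with_stream(cfg$seed, 8L, {
    m <- matrix(stats::rnorm(n_l * n_g, 0, 0.2), n_l, n_g,
                dimnames = list(lines, genes))
    m[amp_lines, truth$anchor] <- stats::rnorm(length(amp_lines), 1.2, 0.2)
    m
  })

  annotation <- data.frame(
    line_id = lines,
    lineage = rep(c("primary_scc", "related_scc"),
                  c(cfg$n_primary, n_l - cfg$n_primary)),
    subtype = rep(c("primary", "related"),
                  c(cfg$n_primary, n_l - cfg$n_primary)),
    hpv_status = "negative", stringsAsFactors = FALSE)
  annotation$absolute_amplified <- lines %in% amp_lines

  mutations <- local({
    rows <- list()
    for (bm in colnames(mut_status)) {
      mut <- lines[mut_status[, bm]]
      if (length(mut)) {
        rows[[bm]] <- data.frame(line_id = mut, gene = bm,
                                 variant_class = "missense",
                                 is_hotspot = TRUE, is_damaging = TRUE,
                                 stringsAsFactors = FALSE)
      }
    }
    # every line carries a silent passenger record so all lines count as
    # mutation-profiled (unknown status is reserved for absent lines)
    rows$filler <- data.frame(line_id = lines, gene = "PASSENGER1",
                              variant_class = "silent",
                              is_hotspot = FALSE, is_damaging = FALSE,
                              stringsAsFactors = FALSE)
    do.call(rbind, c(rows, list(make.row.names = FALSE)))
  })

  drug_lines <- with_stream(cfg$seed, 9L, {
    sort(sample(lines, round(cfg$drug_line_fraction * n_l)))
  })
  drug_response <- with_stream(cfg$seed, 10L, {
    pd <- truth$planted_drugs
    rows <- lapply(seq_len(nrow(pd)), function(i) {
      eff <- effect_vals[drug_lines, pd$target[i]]
      data.frame(drug_id = pd$drug_id[i], drug_name = pd$drug_id[i],
                 target_genes = pd$target[i], line_id = drug_lines,
                 metric = "ln_ic50",
                 value = 0 + pd$slope[i] * eff +
                   stats::rnorm(length(drug_lines), 0, 0.3),
                 stringsAsFactors = FALSE)
    })
    do.call(rbind, c(rows, list(make.row.names = FALSE)))
  })

  # 7-point dose-viability curves for the first planted drug, one curve
  # per drug-profiled line, logistic in log concentration around the
  # line's ln IC50
  dose_curves <- with_stream(cfg$seed, 11L, {
    pd <- truth$planted_drugs[1L, ]
    conc <- 10^seq(-3, 3)  # uM grid
    ln_ic50 <- drug_response$value[drug_response$drug_id == pd$drug_id]
    names(ln_ic50) <- drug_response$line_id[drug_response$drug_id ==
                                              pd$drug_id]
    rows <- lapply(names(ln_ic50), function(l) {
      v <- 1 / (1 + exp(1.2 * (log(conc) - ln_ic50[l]))) +
        stats::rnorm(length(conc), 0, 0.02)
      data.frame(drug_id = pd$drug_id, line_id = l, concentration = conc,
                 viability = pmin(pmax(v, 0), 1), stringsAsFactors = FALSE)
    })
    do.call(rbind, c(rows, list(make.row.names = FALSE)))
  })

  tumours <- with_stream(cfg$seed, 12L, {
    ids <- sprintf("TUM%04d", seq_len(cfg$n_tumours))
    hpv <- rep(c("positive", "unknown", "negative"),
               c(cfg$n_hpv_positive, cfg$n_hpv_unknown,
                 cfg$n_tumours - cfg$n_hpv_positive - cfg$n_hpv_unknown))
    amp <- cfg$amplicon
    u <- stats::runif(cfg$n_tumours)
    anchor_call <- ifelse(u < amp$tumour_amp_rate, 2L,
                          ifelse(u < amp$tumour_gain_rate, 1L, 0L))
    calls <- matrix(0L, cfg$n_tumours, 1L + amp$n_partners,
                    dimnames = list(ids, c(truth$anchor,
                                           truth$amplicon_partners)))
    calls[, truth$anchor] <- anchor_call
    for (p in truth$amplicon_partners) {
      co <- stats::runif(cfg$n_tumours) < amp$partner_coamp_rate
      calls[, p] <- ifelse(co, anchor_call,
                           sample(c(0L, 1L), cfg$n_tumours, TRUE,
                                  c(0.7, 0.3)))
    }
    stratum <- ifelse(anchor_call == 2L, "amplified", "other")
    os <- stats::rexp(cfg$n_tumours,
                      cfg$survival_rates[stratum])
    event <- os <= 60
    os <- pmin(os, 60)
    tp53_mut <- stats::runif(cfg$n_tumours) < 0.822
    df <- data.frame(tumour_id = ids, hpv_status = hpv,
                     os_months = round(os, 2), os_event = event,
                     mutant_genes = ifelse(tp53_mut, "BM1", ""),
                     stringsAsFactors = FALSE)
    for (g in colnames(calls)) df[[paste0("gistic_", g)]] <- calls[, g]
    for (g in colnames(calls)) {
      df[[paste0("log2cn_", g)]] <- round(calls[, g] * 0.8 +
                                            stats::rnorm(cfg$n_tumours,
                                                         0, 0.15), 3)
    }
    df
  })

  bundle <- list(
    effect = screen_matrix(effect_vals, "effect"),
    probability = screen_matrix(prob_vals, "probability"),
    expression = screen_matrix(round(expr_vals, 6), "expression"),
    copy_number = screen_matrix(round(cn_vals, 6), "copy_number"),
    annotation = annotation, mutations = mutations,
    drug_response = drug_response, dose_curves = dose_curves,
    tumours = tumours,
    druggable = gene_set(truth$druggable, "druggable", "druggable"),
    common_essential = gene_set(truth$common_essential, "common_essential",
                                "common_essential"),
    core_fitness = gene_set(truth$core_fitness, "core_fitness",
                            "core_fitness"),
    truth = truth, config = cfg)
  if (!is.null(dir)) write_panel(bundle, dir)
  bundle
}

#' Generate a null panel (no planted effects)
#'
#' Same machinery as [generate_panel()] with zero planted targets,
#' associations, amplicon dependency damping and drug slopes — used for
#' false-positive and type-I calibration.
#'
#' @param cfg A [panel_config()]; its planted effects are zeroed.
#' @param dir Optional output directory.
#' @return A bundle as from [generate_panel()].
#' @export
generate_null_panel <- function(cfg = panel_config(), dir = NULL) {
  stopifnot(inherits(cfg, "panel_config"))
  # keep one nominal "planted" slot so the amplicon anchor and drug target
  # stay defined, but give it a dependent fraction that rounds to zero
  # lines — no gene-level signal is planted anywhere
  cfg$n_planted_targets <- max(1L, cfg$amplicon$anchor_index)
  cfg$planted_dependent_fraction <- 1e-9
  cfg$lowfreq_dependent_fraction <- 1e-9
  cfg$planted_associations <- cfg$planted_associations[0, , drop = FALSE]
  cfg$planted_drugs$slope <- 0
  cfg$expression_rho <- 0
  bundle <- generate_panel(cfg, dir = dir)
  bundle$truth$expected_waterfall_survivors <- character(0)
  bundle$truth$planted_targets <- character(0)
  bundle
}

#' Write a panel bundle to disk in the pipeline's file schemas
#'
#' @param bundle From [generate_panel()].
#' @param dir Output directory.
#' @return `dir`, invisibly.
#' @export
write_panel <- function(bundle, dir) {
  dir.create(dir, showWarnings = FALSE, recursive = TRUE)
  p <- function(f) file.path(dir, f)
  write_matrix(bundle$effect, p("gene_effect.csv"))
  write_matrix(bundle$probability, p("gene_dependency.csv"))
  write_matrix(bundle$expression, p("expression.csv"))
  write_matrix(bundle$copy_number, p("copy_number.csv"))
  data.table::fwrite(bundle$annotation, p("annotation.csv"))
  data.table::fwrite(bundle$mutations, p("mutations.csv"))
  data.table::fwrite(bundle$drug_response, p("drug_response.csv"))
  data.table::fwrite(bundle$dose_curves, p("dose_curves.csv"))
  data.table::fwrite(bundle$tumours, p("tumours.csv"))
  write_gene_set(bundle$druggable, p("druggable.txt"))
  write_gene_set(bundle$common_essential, p("common_essential.txt"))
  write_gene_set(bundle$core_fitness, p("core_fitness.txt"))
  truth <- bundle$truth
  truth$planted_associations <- as.list(truth$planted_associations)
  truth$planted_drugs <- as.list(truth$planted_drugs)
  jsonlite::write_json(truth, p("truth.json"), auto_unbox = FALSE)
  invisible(dir)
}

#' Content hash of a written panel bundle
#'
#' MD5 over the sorted per-file MD5s of every CSV/TXT/JSON in the bundle
#' directory — equal hashes mean byte-identical bundles.
#'
#' @param dir Bundle directory.
#' @return Character MD5 hash.
#' @export
panel_hash <- function(dir) {
  files <- sort(list.files(dir, pattern = "\\.(csv|txt|json)$",
                           full.names = TRUE))
  files <- files[!grepl("meta\\.json$", files)]
  hashes <- tools::md5sum(files)
  tmp <- tempfile()
  on.exit(unlink(tmp))
  writeLines(paste(basename(files), unname(hashes)), tmp)
  unname(tools::md5sum(tmp))
}
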