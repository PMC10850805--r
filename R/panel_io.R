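# Canonical in-memory model for every tabular format the pipeline touches:
# cell-line x gene screen matrices in the DepMap layout, gene lists,
# sample annotations, mutation tables, GDSC-style drug response and
# TCGA-style tumour tables.

SCREEN_ROLES <- c("effect", "probability", "expression", "copy_number")

#' Parse a DepMap-style gene column label
#'
#' DepMap matrices label gene columns as `"SYMBOL (ENTREZ)"`; gene lists and
#' other exports often carry the bare symbol. Both forms are accepted.
#'
#' @param label Character scalar, e.g. `"PAK2 (5062)"` or `"EGFR"`.
#' @return A `gene_id`: list with `symbol` (character) and `entrez`
#'   (positive integer or `NA`).
#' @examples
#' parse_gene_label("PAK2 (5062)")
#' parse_gene_label("EGFR")
#' @export
parse_gene_label <- function(label) {
  if (length(label) != 1L || is.na(label) || !nzchar(trimws(label))) {
    stop("gene label is empty: ", deparse(label), call. = FALSE)
  }
  lab <- trimws(label)
  m <- regmatches(lab, regexec("^(.*?)\\s*\\((\\d+)\\)$", lab))[[1]]
  if (length(m) == 3L) {
    symbol <- trimws(m[2])
    entrez <- as.integer(m[3])
  } else {
    symbol <- lab
    entrez <- NA_integer_
  }
  if (!nzchar(symbol) || grepl("\\s", symbol)) {
    stop("malformed gene label (empty or whitespace-containing symbol): ",
         sQuote(label), call. = FALSE)
  }
  if (!is.na(entrez) && entrez <= 0L) {
    stop("entrez id must be positive in label ", sQuote(label), call. = FALSE)
  }
  gene_id(symbol, entrez)
}

#' @rdname parse_gene_label
#' @param symbol HUGO-style gene symbol (non-empty, no whitespace).
#' @param entrez Optional positive integer Entrez id.
#' @export
gene_id <- function(symbol, entrez = NA_integer_) {
  structure(list(symbol = symbol, entrez = as.integer(entrez)),
            class = "gene_id")
}

#' @export
format.gene_id <- function(x, ...) {
  if (is.na(x$entrez)) x$symbol else sprintf("%s (%d)", x$symbol, x$entrez)
}

#' @export
print.gene_id <- function(x, ...) {
  cat("<gene_id> ", format(x), "\n", sep = "")
  invisible(x)
}

# Vectorised label -> symbol. Equality between datasets falls back to
# symbol-only when entrez is absent on either side, so symbols are the
# join key throughout.
gene_symbols <- function(labels) {
  vapply(labels, function(l) parse_gene_label(l)$symbol, character(1),
         USE.NAMES = FALSE)
}

#' Construct and validate a screen matrix
#'
#' A `screen_matrix` is a numeric cell-line x gene matrix tagged with a
#' `role` that drives validation: dependency probabilities must lie in
#' \[0, 1\]; log2(TPM+1) expression must be non-negative. Missing values are
#' allowed everywhere and are never imputed; downstream denominators count
#' non-missing entries only.
#'
#' @param values Numeric matrix with cell-line rownames and gene-label
#'   colnames (`"SYMBOL (ENTREZ)"` or bare symbols).
#' @param role One of `"effect"`, `"probability"`, `"expression"`,
#'   `"copy_number"`.
#' @return A `screen_matrix` object (numeric matrix with `role` and
#'   `entrez` attributes; colnames are bare symbols).
#' @export
screen_matrix <- function(values, role = c("effect", "probability",
                                           "expression", "copy_number")) {
  role <- match.arg(role)
  if (!is.matrix(values) || !is.numeric(values)) {
    stop("values must be a numeric matrix", call. = FALSE)
  }
  lines <- rownames(values)
  if (is.null(lines) || is.null(colnames(values))) {
    stop("screen matrix needs cell-line rownames and gene colnames",
         call. = FALSE)
  }
  lines <- trimws(lines)
  dup_l <- unique(lines[duplicated(lines)])
  if (length(dup_l)) {
    stop("duplicate cell-line ids: ", paste(dup_l, collapse = ", "),
         call. = FALSE)
  }
  ids <- lapply(colnames(values), parse_gene_label)
  syms <- vapply(ids, `[[`, character(1), "symbol")
  dup_g <- unique(syms[duplicated(syms)])
  if (length(dup_g)) {
    stop("duplicate gene ids: ", paste(dup_g, collapse = ", "), call. = FALSE)
  }
  if (role == "probability") {
    bad <- which(!is.na(values) & (values < 0 | values > 1), arr.ind = TRUE)
    if (nrow(bad)) {
      stop("probability values outside [0, 1] at: ",
           paste(sprintf("(%s, %s)", lines[bad[, 1]], syms[bad[, 2]]),
                 collapse = ", "), call. = FALSE)
    }
  }
  if (role == "expression") {
    bad <- which(!is.na(values) & values < 0, arr.ind = TRUE)
    if (nrow(bad)) {
      stop("expression values below 0 (expected log2(TPM+1)) at: ",
           paste(sprintf("(%s, %s)", lines[bad[, 1]], syms[bad[, 2]]),
                 collapse = ", "), call. = FALSE)
    }
  }
  rownames(values) <- lines
  colnames(values) <- syms
  structure(values, role = role,
            entrez = vapply(ids, `[[`, integer(1), "entrez"),
            class = c("screen_matrix", "matrix", "array"))
}

#' @export
print.screen_matrix <- function(x, ...) {
  cat(sprintf("<screen_matrix role=%s> %d cell lines x %d genes (%d missing)\n",
              attr(x, "role"), nrow(x), ncol(x), sum(is.na(x))))
  invisible(x)
}

matrix_role <- function(x) attr(x, "role")

#' Read a DepMap-layout screen matrix from CSV
#'
#' Expects one header row of gene labels and a first column of cell-line
#' ids (the `CRISPRGeneEffect` / `CRISPRGeneDependency` layout). Blank
#' cells become `NA`. Validation is role-dependent; see [screen_matrix()].
#'
#' @param path Path to a CSV (or TSV with `sep = "\t"`) file.
#' @param role Matrix role; see [screen_matrix()].
#' @param sep Field separator; comma by default.
#' @return A `screen_matrix`.
#' @export
read_matrix <- function(path, role, sep = ",") {
  dt <- data.table::fread(path, sep = sep, header = TRUE,
                          na.strings = c("", "NA"), data.table = FALSE,
                          check.names = FALSE)
  if (ncol(dt) < 2L) stop("matrix file has no gene columns: ", path,
                          call. = FALSE)
  ids <- as.character(dt[[1]])
  vals <- as.matrix(dt[, -1, drop = FALSE])
  storage.mode(vals) <- "double"
  rownames(vals) <- ids
  screen_matrix(vals, role)
}

#' Write a screen matrix (with a provenance sidecar)
#'
#' Emits the same CSV layout [read_matrix()] reads, plus `<path>.meta.json`
#' recording row/column counts and the file's MD5 content hash. The
#' round-trip is bit-identical for finite values and preserves the
#' missingness mask.
#'
#' @param x A `screen_matrix`.
#' @param path Output CSV path.
#' @param id_col Name for the cell-line id column.
#' @return `path`, invisibly.
#' @export
write_matrix <- function(x, path, id_col = "line_id") {
  stopifnot(inherits(x, "screen_matrix"))
  entrez <- attr(x, "entrez")
  labels <- ifelse(is.na(entrez), colnames(x),
                   sprintf("%s (%d)", colnames(x), entrez))
  vals <- unclass(x)[, , drop = FALSE]
  # 17 significant digits round-trip IEEE doubles exactly
  chr <- matrix(ifelse(is.na(vals), "", sprintf("%.17g", vals)),
                nrow(vals), ncol(vals))
  df <- data.frame(rownames(x), chr, check.names = FALSE,
                   stringsAsFactors = FALSE)
  names(df) <- c(id_col, labels)
  data.table::fwrite(df, path, na = "", quote = FALSE)
  write_sidecar(path, n_rows = nrow(x), n_cols = ncol(x),
                role = matrix_role(x))
  invisible(path)
}

write_sidecar <- function(path, ...) {
  meta <- c(list(...), list(md5 = unname(tools::md5sum(path))))
  jsonlite::write_json(meta, paste0(path, ".meta.json"), auto_unbox = TRUE)
  invisible(NULL)
}

#' Construct a provenance-tagged gene set
#'
#' @param members Character vector of gene labels (bare symbols or
#'   `"SYMBOL (ENTREZ)"`); de-duplicated on symbol.
#' @param name Set name.
#' @param provenance One of `"druggable"`, `"common_essential"`,
#'   `"core_fitness"`, `"prioritized"`, `"custom"`.
#' @param allow_empty Permit an empty membership (default `FALSE`).
#' @return A `gene_set`: character vector of symbols with `name` and
#'   `provenance` attributes.
#' @export
gene_set <- function(members, name = "set",
                     provenance = c("custom", "druggable", "common_essential",
                                    "core_fitness", "prioritized"),
                     allow_empty = FALSE) {
  provenance <- match.arg(provenance)
  syms <- if (length(members)) unique(gene_symbols(members)) else character(0)
  if (!length(syms) && !allow_empty) {
    stop("gene set ", sQuote(name), " is empty", call. = FALSE)
  }
  structure(syms, name = name, provenance = provenance,
            class = c("gene_set", "character"))
}

#' @export
print.gene_set <- function(x, ...) {
  cat(sprintf("<gene_set %s> %d genes (%s)\n", attr(x, "name"), length(x),
              attr(x, "provenance")))
  invisible(x)
}

#' Read a gene list (one symbol per line)
#'
#' Lines starting with `#` are comments; duplicates are dropped and their
#' count reported via `message()`.
#'
#' @inheritParams gene_set
#' @param path Text file with one symbol (or `"SYMBOL (ENTREZ)"`) per line.
#' @return A `gene_set`.
#' @export
read_gene_set <- function(path, name = basename(path),
                          provenance = "custom", allow_empty = FALSE) {
  lines <- readLines(path, warn = FALSE)
  lines <- trimws(lines)
  lines <- lines[nzchar(lines) & !startsWith(lines, "#")]
  syms <- if (length(lines)) gene_symbols(lines) else character(0)
  n_dup <- length(syms) - length(unique(syms))
  if (n_dup > 0) {
    message(sprintf("read_gene_set(%s): dropped %d duplicate entr%s",
                    name, n_dup, if (n_dup == 1L) "y" else "ies"))
  }
  gene_set(unique(syms), name = name, provenance = provenance,
           allow_empty = allow_empty)
}

#' Write a gene set as a one-symbol-per-line list
#' @param x A `gene_set`.
#' @param path Output path.
#' @export
write_gene_set <- function(x, path) {
  writeLines(as.character(x), path)
  write_sidecar(path, n_genes = length(x), name = attr(x, "name"),
                provenance = attr(x, "provenance"))
  invisible(path)
}

#' Read a cell-line / sample annotation table
#'
#' Expects columns `line_id`, `lineage`, `subtype`, `hpv_status`
#' (values `negative`/`positive`/`unknown`; missing column implies
#' `unknown`).
#'
#' @param path CSV path.
#' @return data.frame with unique `line_id`.
#' @export
read_annotation <- function(path) {
  df <- data.table::fread(path, data.table = FALSE, na.strings = c("", "NA"))
  need <- c("line_id", "lineage")
  miss <- setdiff(need, names(df))
  if (length(miss)) {
    stop("annotation file missing columns: ", paste(miss, collapse = ", "),
         call. = FALSE)
  }
  if (!"subtype" %in% names(df)) df$subtype <- NA_character_
  if (!"hpv_status" %in% names(df)) df$hpv_status <- "unknown"
  df$hpv_status[is.na(df$hpv_status)] <- "unknown"
  bad <- setdiff(unique(df$hpv_status), c("negative", "positive", "unknown"))
  if (length(bad)) {
    stop("invalid hpv_status values: ", paste(bad, collapse = ", "),
         call. = FALSE)
  }
  dup <- unique(df$line_id[duplicated(df$line_id)])
  if (length(dup)) {
    stop("duplicate line_id in annotation: ", paste(dup, collapse = ", "),
         call. = FALSE)
  }
  df
}

#' Select panel members by annotation rules
#'
#' `rules` is a list of clauses; each clause is a named list of
#' field = allowed-values pairs. A sample is selected when it satisfies
#' every pair of at least one clause (conjunction within a clause, union
#' across clauses). An empty `rules` list selects everything. Input order
#' is preserved.
#'
#' @param annot Annotation data.frame (first column taken as the id when no
#'   `line_id`/`tumour_id` column is present).
#' @param rules List of clauses, e.g.
#'   `list(list(lineage = "HNSCC", hpv_status = "negative"),
#'         list(lineage = "ESCC"))`.
#' @return Character vector of selected ids, in input order.
#' @export
subset_panel <- function(annot, rules = list()) {
  id_col <- intersect(c("line_id", "tumour_id"), names(annot))
  id_col <- if (length(id_col)) id_col[1] else names(annot)[1]
  ids <- as.character(annot[[id_col]])
  if (!length(rules)) return(ids)
  if (!is.list(rules[[1]])) rules <- list(rules)  # single clause shorthand
  keep <- rep(FALSE, nrow(annot))
  for (clause in rules) {
    unknown <- setdiff(names(clause), names(annot))
    if (length(unknown)) {
      stop("subset rule references unknown field(s): ",
           paste(unknown, collapse = ", "), call. = FALSE)
    }
    sel <- rep(TRUE, nrow(annot))
    for (field in names(clause)) {
      sel <- sel & (annot[[field]] %in% clause[[field]])
    }
    keep <- keep | sel
  }
  ids[keep]
}

#' Read a flat mutation table
#'
#' Columns: `line_id`, `gene`, `variant_class` (optional), and at least one
#' of the logical flags `is_hotspot` / `is_damaging`. Multiple rows per
#' (line, gene) are allowed (one per variant).
#'
#' @param path CSV path.
#' @return data.frame with `gene` reduced to bare symbols and both flag
#'   columns present (absent one filled with `FALSE`).
#' @export
read_mutations <- function(path) {
  df <- data.table::fread(path, data.table = FALSE, na.strings = c("", "NA"))
  need <- c("line_id", "gene")
  miss <- setdiff(need, names(df))
  if (length(miss)) {
    stop("mutation file missing columns: ", paste(miss, collapse = ", "),
         call. = FALSE)
  }
  if (!any(c("is_hotspot", "is_damaging") %in% names(df))) {
    stop("mutation file needs is_hotspot and/or is_damaging flags",
         call. = FALSE)
  }
  for (flag in c("is_hotspot", "is_damaging")) {
    if (!flag %in% names(df)) df[[flag]] <- FALSE
    df[[flag]] <- as.logical(df[[flag]])
    df[[flag]][is.na(df[[flag]])] <- FALSE
  }
  if (!"variant_class" %in% names(df)) df$variant_class <- NA_character_
  df$gene <- gene_symbols(as.character(df$gene))
  df
}

#' Read a GDSC-style long drug-response table
#'
#' Columns: `drug_id`, `drug_name`, `target_genes` (`;`-separated symbols),
#' `line_id`, `metric` (`ln_ic50` or `auc`), `value`; optionally
#' `concentration` and `viability` columns for per-dose points (one row per
#' dose, `value` repeated).
#'
#' @param path CSV path.
#' @return data.frame; AUC rows validated to lie in \[0, 1\].
#' @export
read_drug_response <- function(path) {
  df <- data.table::fread(path, data.table = FALSE, na.strings = c("", "NA"))
  need <- c("drug_id", "line_id", "metric", "value")
  miss <- setdiff(need, names(df))
  if (length(miss)) {
    stop("drug-response file missing columns: ", paste(miss, collapse = ", "),
         call. = FALSE)
  }
  bad_metric <- setdiff(unique(df$metric), c("ln_ic50", "auc"))
  if (length(bad_metric)) {
    stop("unknown response metric(s): ", paste(bad_metric, collapse = ", "),
         call. = FALSE)
  }
  auc <- df$metric == "auc" & !is.na(df$value)
  if (any(auc & (df$value < 0 | df$value > 1))) {
    stop("auc values outside [0, 1]", call. = FALSE)
  }
  if (!"target_genes" %in% names(df)) df$target_genes <- NA_character_
  if (!"drug_name" %in% names(df)) df$drug_name <- as.character(df$drug_id)
  df
}

#' Read a TCGA-style per-tumour table
#'
#' One row per tumour: `tumour_id`, `hpv_status`, `os_months`, `os_event`,
#' plus per-gene GISTIC call columns named `gistic_<SYMBOL>` (integers in
#' -2..2), optional `log2cn_<SYMBOL>` columns, and an optional
#' `mutant_genes` `;`-separated list.
#'
#' @param path CSV path.
#' @return data.frame; GISTIC codes validated against the 5-level set and
#'   `os_months` against non-negativity.
#' @export
read_tumours <- function(path) {
  df <- data.table::fread(path, data.table = FALSE, na.strings = c("", "NA"))
  need <- c("tumour_id", "hpv_status")
  miss <- setdiff(need, names(df))
  if (length(miss)) {
    stop("tumour file missing columns: ", paste(miss, collapse = ", "),
         call. = FALSE)
  }
  gcols <- grep("^gistic_", names(df), value = TRUE)
  for (g in gcols) {
    v <- df[[g]]
    if (any(!is.na(v) & !(v %in% -2:2))) {
      stop("GISTIC codes outside {-2..2} in column ", g, call. = FALSE)
    }
  }
  if ("os_months" %in% names(df) &&
      any(!is.na(df$os_months) & df$os_months < 0)) {
    stop("negative os_months", call. = FALSE)
  }
  df
}

#' Extract the GISTIC call matrix from a tumour table
#'
#' @param tumours data.frame from [read_tumours()] (columns
#'   `gistic_<SYMBOL>`).
#' @return Integer matrix (tumour x gene) of GISTIC codes.
#' @export
gistic_matrix <- function(tumours) {
  gcols <- grep("^gistic_", names(tumours), value = TRUE)
  m <- as.matrix(tumours[, gcols, drop = FALSE])
  rownames(m) <- tumours$tumour_id
  colnames(m) <- sub("^gistic_", "", gcols)
  storage.mode(m) <- "integer"
  m
}
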