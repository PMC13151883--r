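#' Default column schema for variant tables
#'
#' Maps canonical field names to column names in a tab-separated variant
#' table. Override entries to read tables with different headers, e.g.
#' `variant_schema(af = "gnomad_af")`.
#'
#' @param ... named character overrides, one per canonical field.
#' @return named character vector mapping canonical names to file columns.
#' @export
variant_schema <- function(...) {
  schema <- c(
    variant_id = "variant_id", gene_id = "gene_id",
    af = "af", loeuf = "loeuf", ccr = "ccr", fdr_tada_dd = "fdr_tada_dd",
    obs_lof = "obs_lof", exp_lof = "exp_lof",
    inheritance_label = "inheritance_label",
    de_novo_score = "de_novo_score", predicted_class = "predicted_class"
  )
  over <- c(...)
  if (length(over)) {
    unknown <- setdiff(names(over), names(schema))
    if (length(unknown)) {
      stop_tadard("unknown schema field(s): %s", paste(unknown, collapse = ", "))
    }
    schema[names(over)] <- over
  }
  schema
}

parse_numeric_column <- function(x, col, lines) {
  x[!is.na(x) & x == ""] <- NA
  out <- suppressWarnings(as.numeric(x))
  bad <- !is.na(x) & is.na(out)
  if (any(bad)) {
    stop_tadard("column '%s': unparseable numeric value '%s' at line %d",
                col, x[which(bad)[1]], lines[which(bad)[1]])
  }
  out
}

normalise_label <- function(x, allowed, col, default) {
  x <- tolower(trimws(as.character(x)))
  x <- gsub("[ -]", "_", x)
  x[is.na(x) | x == ""] <- default
  bad <- !x %in% allowed
  if (any(bad)) {
    stop_tadard("column '%s': invalid value '%s' (allowed: %s)",
                col, x[which(bad)[1]], paste(allowed, collapse = ", "))
  }
  x
}

#' Read an annotated variant table
#'
#' Reads a tab-separated table with one row per offspring variant carrying the
#' six classifier covariates (allele frequency, LOEUF, CCR, FDR_TADA_DD,
#' obs_lof, exp_lof). Missing covariate cells become `NA`; inheritance labels
#' are parsed case-insensitively into `de_novo`, `inherited` or `unknown`.
#'
#' @param path path to a tab-separated file with a header row.
#' @param schema column-name map from [variant_schema()].
#' @return a `data.frame` of variants with canonical column names; optional
#'   columns `de_novo_score` (numeric or `NA`) and `predicted_class`
#'   (`likely_de_novo` / `likely_inherited` / `unset`) are always present.
#' @export
read_variant_table <- function(path, schema = variant_schema()) {
  if (!file.exists(path)) stop_tadard("variant table not found: %s", path)
  raw <- utils::read.delim(path, colClasses = "character", check.names = FALSE,
                           na.strings = c("NA", ""))
  required <- c("variant_id", "gene_id", covariate_names())
  for (field in required) {
    if (!schema[[field]] %in% names(raw)) {
      stop_tadard("variant table %s is missing required column '%s'",
                  path, schema[[field]])
    }
  }
  lines <- seq_len(nrow(raw)) + 1L  # header is line 1
  out <- data.frame(
    variant_id = as.character(raw[[schema[["variant_id"]]]]),
    gene_id = as.character(raw[[schema[["gene_id"]]]]),
    stringsAsFactors = FALSE
  )
  for (cov in covariate_names()) {
    out[[cov]] <- parse_numeric_column(raw[[schema[[cov]]]], schema[[cov]], lines)
  }
  lab_col <- schema[["inheritance_label"]]
  out$inheritance_label <- if (lab_col %in% names(raw)) {
    normalise_label(raw[[lab_col]], c("de_novo", "inherited", "unknown"),
                    lab_col, "unknown")
  } else "unknown"
  score_col <- schema[["de_novo_score"]]
  out$de_novo_score <- if (score_col %in% names(raw)) {
    parse_numeric_column(raw[[score_col]], score_col, lines)
  } else NA_real_
  pred_col <- schema[["predicted_class"]]
  out$predicted_class <- if (pred_col %in% names(raw)) {
    normalise_label(raw[[pred_col]], c("likely_de_novo", "likely_inherited", "unset"),
                    pred_col, "unset")
  } else "unset"
  validate_variants(out)
}

#' Validate a variant data frame
#'
#' Checks range invariants: `af`, `fdr_tada_dd` and `de_novo_score` in
#' \[0, 1\]; `ccr` in \[0, 100\]; `loeuf`, `obs_lof`, `exp_lof` nonnegative;
#' a `predicted_class` other than `unset` requires a de novo score.
#'
#' @param variants variant `data.frame` as returned by [read_variant_table()].
#' @return the input, invisibly checked (returned for piping).
#' @export
validate_variants <- function(variants) {
  assert_fraction(variants$af, "af", allow_na = TRUE)
  assert_fraction(variants$fdr_tada_dd, "fdr_tada_dd", allow_na = TRUE)
  assert_fraction(variants$de_novo_score, "de_novo_score", allow_na = TRUE)
  if (any(!is.na(variants$ccr) & (variants$ccr < 0 | variants$ccr > 100))) {
    stop_tadard("`ccr` must lie in [0, 100]")
  }
  for (cov in c("loeuf", "obs_lof", "exp_lof")) {
    if (any(!is.na(variants[[cov]]) & variants[[cov]] < 0)) {
      stop_tadard("`%s` must be nonnegative", cov)
    }
  }
  classified <- variants$predicted_class != "unset"
  if (any(classified & is.na(variants$de_novo_score))) {
    stop_tadard("variant '%s' has a predicted class but no de novo score",
                variants$variant_id[which(classified & is.na(variants$de_novo_score))[1]])
  }
  variants
}

#' Write a variant table
#'
#' Inverse of [read_variant_table()]: writes the canonical tab-separated
#' dialect (header row, `NA` for missing cells, no quoting), so that reading
#' the file back reproduces all fields.
#'
#' @param variants variant `data.frame`.
#' @param path output path.
#' @return `path`, invisibly.
#' @export
write_variant_table <- function(variants, path) {
  utils::write.table(format_full_precision(variants), path, sep = "\t",
                     quote = FALSE, row.names = FALSE, na = "NA")
  invisible(path)
}

# 17 significant digits: enough for a double to survive a text round trip.
format_full_precision <- function(df) {
  for (col in names(df)) {
    if (is.double(df[[col]])) {
      txt <- sprintf("%.17g", df[[col]])
      txt[is.na(df[[col]])] <- NA
      df[[col]] <- txt
    }
  }
  df
}

#' Read a gene table
#'
#' Gene tables carry one row per gene: `gene_id` and the baseline mutation
#' rate `mu` are required; `family_bf` (per-gene Bayes factor from the
#' family-based analysis), `risk_label` (simulation truth / prior-evidence
#' flag) and `case_variant_count` are optional.
#'
#' @param path path to a tab-separated file with a header row.
#' @return a `data.frame` with columns `gene_id`, `mu`, `family_bf`,
#'   `risk_label`, `case_variant_count` (missing optionals filled with `NA`).
#' @export
read_gene_table <- function(path) {
  if (!file.exists(path)) stop_tadard("gene table not found: %s", path)
  raw <- utils::read.delim(path, colClasses = "character", check.names = FALSE,
                           na.strings = c("NA", ""))
  for (field in c("gene_id", "mu")) {
    if (!field %in% names(raw)) {
      stop_tadard("gene table %s is missing required column '%s'", path, field)
    }
  }
  lines <- seq_len(nrow(raw)) + 1L
  out <- data.frame(gene_id = as.character(raw$gene_id), stringsAsFactors = FALSE)
  out$mu <- parse_numeric_column(raw$mu, "mu", lines)
  if (any(is.na(out$mu) | out$mu <= 0)) {
    stop_tadard("`mu` must be positive for every gene")
  }
  out$family_bf <- if ("family_bf" %in% names(raw)) {
    parse_numeric_column(raw$family_bf, "family_bf", lines)
  } else NA_real_
  if (any(!is.na(out$family_bf) & out$family_bf <= 0)) {
    stop_tadard("`family_bf` must be positive when present")
  }
  out$risk_label <- if ("risk_label" %in% names(raw)) {
    as.logical(parse_numeric_column(
      ifelse(tolower(raw$risk_label) %in% c("true", "false"),
             as.character(as.integer(tolower(raw$risk_label) == "true")),
             raw$risk_label), "risk_label", lines))
  } else NA
  out$case_variant_count <- if ("case_variant_count" %in% names(raw)) {
    parse_numeric_column(raw$case_variant_count, "case_variant_count", lines)
  } else NA_real_
  out
}

#' Write a gene table
#'
#' @param genes gene `data.frame` as from [read_gene_table()].
#' @param path output path.
#' @return `path`, invisibly.
#' @export
write_gene_table <- function(genes, path) {
  utils::write.table(format_full_precision(genes), path, sep = "\t",
                     quote = FALSE, row.names = FALSE, na = "NA")
  invisible(path)
}

#' Keep ultra-rare variants
#'
#' Restricts to variants with population allele frequency strictly below
#' `af_max` (default 0.1%). A missing allele frequency means the variant is
#' absent from the population reference, which is the strongest rarity
#' evidence, so missing `af` is treated as 0 and kept.
#'
#' @param variants variant `data.frame`.
#' @param af_max exclusive upper bound on allele frequency, in (0, 1].
#' @return the subset of rows with `af < af_max`, order preserved.
#' @export
filter_ultra_rare <- function(variants, af_max = 0.001) {
  if (!is.numeric(af_max) || length(af_max) != 1 || af_max <= 0 || af_max > 1) {
    stop_tadard("`af_max` must be a single value in (0, 1]")
  }
  af <- variants$af
  af[is.na(af)] <- 0
  variants[af < af_max, , drop = FALSE]
}

#' Aggregate classified variants into per-gene counts
#'
#' Tallies, for each gene present in the input, the number of likely-de-novo
#' (`x_d`) and likely-inherited (`x_h`) variants. Every record must carry a
#' prediction; genes with no classified variants are absent from the output.
#'
#' @param variants variant `data.frame` with `predicted_class` set.
#' @return a `data.frame` with columns `gene_id`, `x_d`, `x_h`, one row per
#'   distinct gene in order of first appearance.
#' @export
aggregate_gene_counts <- function(variants) {
  unset <- variants$predicted_class == "unset" | is.na(variants$predicted_class)
  if (any(unset)) {
    stop_tadard("variant '%s' has no predicted class; classify before aggregating",
                variants$variant_id[which(unset)[1]])
  }
  genes <- unique(variants$gene_id)
  gi <- factor(variants$gene_id, levels = genes)
  x_d <- tapply(variants$predicted_class == "likely_de_novo", gi, sum)
  x_h <- tapply(variants$predicted_class == "likely_inherited", gi, sum)
  data.frame(gene_id = genes,
             x_d = as.integer(x_d), x_h = as.integer(x_h),
             stringsAsFactors = FALSE, row.names = NULL)
}
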