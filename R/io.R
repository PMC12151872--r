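# File dialects: tab-separated, UTF-8, `NA` (or empty) for missing, no
# quoting.  Every writer produces files its paired reader accepts
# unchanged.

parse_column <- function(values, type, col, path) {
  n <- length(values)
  conv <- switch(
    type,
    character = values,
    numeric = suppressWarnings(as.numeric(values)),
    integer = suppressWarnings(as.integer(values)),
    logical = {
      v <- rep(NA, n)
      v[values %in% c("1", "TRUE", "true")] <- TRUE
      v[values %in% c("0", "FALSE", "false")] <- FALSE
      v
    },
    stop_schema(sprintf("unknown schema type '%s'", type)))
  bad <- which(is.na(conv) & !is.na(values))
  if (length(bad))
    stop_schema(sprintf(
      "%s: line %d, column '%s': cannot parse '%s' as %s",
      path, bad[1] + 1L, col, values[bad[1]], type))
  conv
}

#' Read and validate a tab-separated table against a schema
#'
#' The header must contain every schema column (extras are kept as
#' character).  Cells are typed per the schema; `NA` or an empty cell is
#' missing.  Errors name the file, 1-based line and column.
#'
#' @param path File path.
#' @param schema Named character vector mapping column name to one of
#'   `"character"`, `"numeric"`, `"integer"`, `"logical"`.
#' @param key Optional column that must be unique.
#' @param required Columns that may not contain missing values
#'   (defaults to every schema column).
#' @return Data frame with typed columns.
#' @export
read_table <- function(path, schema, key = NULL, required = names(schema)) {
  if (!file.exists(path))
    stop_input(sprintf("file not found: %s", path))
  df <- utils::read.delim(path, colClasses = "character",
                          na.strings = c("NA", ""), check.names = FALSE,
                          stringsAsFactors = FALSE)
  missing_cols <- setdiff(names(schema), names(df))
  if (length(missing_cols))
    stop_schema(sprintf("%s: missing column(s): %s", path,
                        paste(missing_cols, collapse = ", ")))
  for (col in names(schema))
    df[[col]] <- parse_column(df[[col]], schema[[col]], col, path)
  for (col in required) {
    bad <- which(is.na(df[[col]]))
    if (length(bad))
      stop_schema(sprintf("%s: line %d: missing value in required column '%s'",
                          path, bad[1] + 1L, col))
  }
  if (!is.null(key)) {
    dup <- which(duplicated(df[[key]]))
    if (length(dup))
      stop_schema(sprintf("%s: line %d: duplicate key '%s' in column '%s'",
                          path, dup[1] + 1L, df[[key]][dup[1]], key))
  }
  df
}

#' Write a data frame in the package's TSV dialect
#' @param df Data frame.
#' @param path Output path.
#' @export
write_tsv <- function(df, path) {
  utils::write.table(df, path, sep = "\t", quote = FALSE,
                     row.names = FALSE, na = "NA")
  invisible(path)
}

#' Read a per-strain lifespan phenotype table
#'
#' Columns: `strain_id`, `lifespan_change_pct` (percent change of
#' replicative lifespan vs. wild type), `n_cells`.
#' @param path File path.
#' @return Data frame `strain_id`, `lifespan_change`, `n_cells`.
#' @export
read_phenotypes <- function(path) {
  df <- read_table(path,
                   c(strain_id = "character",
                     lifespan_change_pct = "numeric",
                     n_cells = "integer"),
                   key = "strain_id")
  if (any(df$n_cells < 0))
    stop_schema(sprintf("%s: n_cells must be non-negative", path))
  data.frame(strain_id = df$strain_id,
             lifespan_change = df$lifespan_change_pct,
             n_cells = df$n_cells, stringsAsFactors = FALSE)
}

#' @rdname read_phenotypes
#' @param phenotypes Data frame `strain_id`, `lifespan_change`, `n_cells`.
#' @export
write_phenotypes <- function(phenotypes, path) {
  write_tsv(data.frame(strain_id = phenotypes$strain_id,
                       lifespan_change_pct = phenotypes$lifespan_change,
                       n_cells = phenotypes$n_cells), path)
}

#' Read an expression compendium matrix
#'
#' TSV matrix: first column `gene_id`, remaining columns strain ids,
#' cells are expression log2 fold changes vs. wild type (`NA`/empty =
#' missing).  Returned transposed to the strains-x-genes orientation
#' used by [screen_genes()].
#' @param path File path.
#' @return Numeric matrix, strains x genes.
#' @export
read_compendium <- function(path) {
  df <- utils::read.delim(path, check.names = FALSE,
                          na.strings = c("NA", ""),
                          stringsAsFactors = FALSE)
  if (names(df)[1] != "gene_id")
    stop_schema(sprintf("%s: first column must be 'gene_id'", path))
  if (anyDuplicated(df$gene_id))
    stop_schema(sprintf("%s: duplicate gene_id", path))
  if (anyDuplicated(names(df)[-1]))
    stop_schema(sprintf("%s: duplicate strain columns", path))
  m <- as.matrix(df[, -1, drop = FALSE])
  if (!is.numeric(m))
    stop_schema(sprintf("%s: expression values must be numeric", path))
  rownames(m) <- df$gene_id
  t(m)
}

#' @rdname read_compendium
#' @param compendium Strains-x-genes numeric matrix.
#' @export
write_compendium <- function(compendium, path) {
  m <- t(compendium)
  df <- data.frame(gene_id = rownames(m), m, check.names = FALSE,
                   stringsAsFactors = FALSE)
  write_tsv(df, path)
}

#' Read lifespan records
#'
#' Columns: `group`, `lifespan` (> 0), `observed` (0/1; 0 =
#' right-censored).
#' @param path File path.
#' @return Data frame `group`, `lifespan`, `observed` (logical).
#' @export
read_lifespans <- function(path) {
  df <- read_table(path, c(group = "character", lifespan = "numeric",
                           observed = "logical"))
  if (any(df$lifespan <= 0))
    stop_schema(sprintf("%s: lifespans must be positive", path))
  df
}

#' @rdname read_lifespans
#' @param records Lifespan record data frame.
#' @export
write_lifespans <- function(records, path) {
  write_tsv(data.frame(group = records$group, lifespan = records$lifespan,
                       observed = as.integer(records$observed)), path)
}

#' Read precomputed per-gene differential-expression statistics
#'
#' Columns: `gene_id`, `log2fc`, `p_value`, optional `q_value` —
#' supplied tables (e.g. from an external DE caller) take precedence
#' over the built-in Welch fallback.
#' @param path File path.
#' @return Data frame suitable for [call_degs()].
#' @export
read_deg_stats <- function(path) {
  schema <- c(gene_id = "character", log2fc = "numeric",
              p_value = "numeric")
  header <- names(utils::read.delim(path, nrows = 1, check.names = FALSE))
  if ("q_value" %in% header) schema <- c(schema, q_value = "numeric")
  read_table(path, schema, key = "gene_id")
}

#' Read a long-form replicate FPKM table
#'
#' Columns: `gene_id`, `group` (exactly two levels), `replicate`,
#' `fpkm`.  Returns the experiment container used by
#' [compute_deg_stats()], with the control group chosen as the first
#' level unless named.
#' @param path File path.
#' @param control Which `group` value is the control (default: first
#'   group in file order).
#' @return List `genes`, `fpkm_control`, `fpkm_treatment`.
#' @export
read_expression <- function(path, control = NULL) {
  df <- read_table(path, c(gene_id = "character", group = "character",
                           replicate = "character", fpkm = "numeric"))
  if (any(df$fpkm < 0))
    stop_schema(sprintf("%s: FPKM must be non-negative", path))
  groups <- unique(df$group)
  if (length(groups) != 2L)
    stop_schema(sprintf("%s: expected exactly 2 groups, found %d",
                        path, length(groups)))
  control <- control %||% groups[1]
  if (!control %in% groups)
    stop_schema(sprintf("%s: control group '%s' not present", path, control))
  treatment <- setdiff(groups, control)
  wide <- function(g) {
    sub <- df[df$group == g, , drop = FALSE]
    m <- stats::xtabs(fpkm ~ gene_id + replicate, data = sub)
    m <- matrix(as.numeric(m), nrow = nrow(m), dimnames = dimnames(m))
    m
  }
  ctrl <- wide(control)
  treat <- wide(treatment)
  genes <- intersect(rownames(ctrl), rownames(treat))
  list(genes = genes,
       fpkm_control = ctrl[genes, , drop = FALSE],
       fpkm_treatment = treat[genes, , drop = FALSE])
}

#' @rdname read_expression
#' @param experiment Experiment list (`genes`, `fpkm_control`,
#'   `fpkm_treatment`).
#' @param control_label,treatment_label Group labels to write.
#' @export
write_expression <- function(experiment, path, control_label = "control",
                             treatment_label = "treatment") {
  long_one <- function(m, label) {
    data.frame(gene_id = rep(experiment$genes, ncol(m)),
               group = label,
               replicate = rep(colnames(m) %||% paste0("rep", seq_len(ncol(m))),
                               each = nrow(m)),
               fpkm = as.numeric(m), stringsAsFactors = FALSE)
  }
  write_tsv(rbind(long_one(experiment$fpkm_control, control_label),
                  long_one(experiment$fpkm_treatment, treatment_label)),
            path)
}

#' Read a per-gene promoter-state label table
#'
#' Columns: `gene_id`, `state` in `{active, inactive}`.
#' @param path File path.
#' @return Data frame `gene_id`, `state`.
#' @export
read_promoter_states <- function(path) {
  df <- read_table(path, c(gene_id = "character", state = "character"),
                   key = "gene_id")
  bad <- which(!df$state %in% c("active", "inactive"))
  if (length(bad))
    stop_schema(sprintf("%s: line %d: state must be 'active' or 'inactive'",
                        path, bad[1] + 1L))
  df
}

#' Read a gene-to-term annotation table
#'
#' Columns: `gene_id`, `term_id`; multiple rows per gene.
#' @param path File path.
#' @return Data frame `gene_id`, `term_id`.
#' @export
read_gene_terms <- function(path) {
  read_table(path, c(gene_id = "character", term_id = "character"))
}

#' Read dose-response points
#'
#' Columns: `dose` (e.g. expression fold change or RNAi fraction) and
#' `response` (lifespan or percent extension).
#' @param path File path.
#' @return Data frame `dose`, `response`.
#' @export
read_dose_response <- function(path) {
  read_table(path, c(dose = "numeric", response = "numeric"))
}

#' Read a gene TSS table
#'
#' Columns: `gene_id`, `chrom`, `tss` (1-based position), `strand`
#' (`+`/`-`).
#' @param path File path.
#' @return Data frame `gene_id`, `chrom`, `tss`, `strand`.
#' @export
read_tss_table <- function(path) {
  df <- read_table(path, c(gene_id = "character", chrom = "character",
                           tss = "integer", strand = "character"),
                   key = "gene_id")
  if (any(df$tss < 1))
    stop_schema(sprintf("%s: tss positions are 1-based (>= 1)", path))
  bad <- which(!df$strand %in% c("+", "-"))
  if (length(bad))
    stop_schema(sprintf("%s: line %d: strand must be '+' or '-'",
                        path, bad[1] + 1L))
  df
}

#' Write screen results
#' @param screen A `"screen_result"` from [screen_genes()].
#' @param path Output path.
#' @export
write_screen_results <- function(screen, path) {
  cols <- c("rank", "gene_id", "slope", "intercept", "slope_se",
            "t_stat", "p_value", "q_value", "n_strains_used")
  write_tsv(screen$results[, cols, drop = FALSE], path)
}
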