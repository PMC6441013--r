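#' Read a differential-expression table
#'
#' Accepts CSV or TSV with columns `transcript_id`, `gene_symbol`, an effect
#' column (`log2_fold_change`, `log2FC`, `b` or `beta` — which scale the
#' effect column is on must be known to the caller; it is renamed, not
#' transformed), `p_value`/`pval` and `q_value`/`qval`.
#'
#' @param path Path to the table.
#' @return A tibble with canonical column names: `transcript_id`,
#'   `gene_symbol`, `log2_fold_change`, `p_value`, `q_value`.
#' @export
read_de_table <- function(path) {
  delim <- if (grepl("\\.tsv$", path, ignore.case = TRUE)) "\t" else ","
  raw <- readr::read_delim(path, delim = delim, show_col_types = FALSE)
  alias <- list(
    transcript_id = c("transcript_id", "target_id"),
    gene_symbol = c("gene_symbol", "symbol", "ext_gene"),
    log2_fold_change = c("log2_fold_change", "log2fc", "b", "beta"),
    p_value = c("p_value", "pval", "p"),
    q_value = c("q_value", "qval", "q")
  )
  out <- purrr::imap(alias, function(cands, canon) {
    hit <- intersect(cands, tolower(names(raw)))
    if (length(hit) == 0) {
      abort(paste0("missing column for ", canon, " (any of: ",
                   paste(cands, collapse = ", "), ")"),
            class = "spherotax_invalid_input")
    }
    raw[[match(hit[1], tolower(names(raw)))]]
  })
  as_tibble(out)
}

validate_de <- function(records) {
  req <- c("transcript_id", "gene_symbol", "log2_fold_change", "p_value",
           "q_value")
  if (!is.data.frame(records) || !all(req %in% names(records))) {
    abort(paste0("DE records need columns: ", paste(req, collapse = ", ")),
          class = "spherotax_invalid_input")
  }
  if (any(records$q_value < 0, na.rm = TRUE)) {
    abort("q-values must be non-negative", class = "spherotax_domain_error")
  }
  invisible(records)
}

#' Filter differential-expression records by FDR and fold change
#'
#' Keeps records significant at `q_value < fdr_cutoff` (strict) with an
#' absolute linear fold change of at least `min_abs_fold_change`, i.e.
#' `|log2FC| >= log2(min_abs_fold_change)`.
#'
#' @param records DE tibble (see [read_de_table()] for columns).
#' @param fdr_cutoff FDR threshold, strict inequality (default 0.05).
#' @param min_abs_fold_change Minimum absolute fold change on the linear
#'   scale (default 2).
#' @return The significant subset, same columns.
#' @export
filter_de <- function(records, fdr_cutoff = 0.05, min_abs_fold_change = 2) {
  validate_de(records)
  records %>%
    filter(
      .data$q_value < fdr_cutoff,
      abs(.data$log2_fold_change) >= log2(min_abs_fold_change)
    )
}

#' Collapse transcripts to genes by symbol
#'
#' In cases of gene-symbol collision, the transcript with the lowest raw
#' p-value is selected; ties break to the lexicographically smallest
#' transcript id. Records with a missing or empty gene symbol are dropped
#' and reported in the `skipped` attribute.
#'
#' @param records DE tibble.
#' @return One record per gene symbol, with attribute `skipped` holding the
#'   symbol-less records.
#' @export
collapse_by_symbol <- function(records) {
  validate_de(records)
  bad <- is.na(records$gene_symbol) | records$gene_symbol == ""
  skipped <- records[bad, , drop = FALSE]
  if (nrow(skipped) > 0) {
    warn(sprintf("%d record(s) without a gene symbol were skipped",
                 nrow(skipped)))
  }
  out <- records[!bad, , drop = FALSE] %>%
    arrange(.data$gene_symbol, .data$p_value, .data$transcript_id) %>%
    group_by(.data$gene_symbol) %>%
    dplyr::slice(1) %>%
    ungroup()
  attr(out, "skipped") <- skipped
  out
}

#' Signed negative-log rank scores for pre-ranked enrichment
#'
#' For gene-level records, the ranking score is the negative log (base 10 by
#' default) of the FDR-adjusted p-value, signed by the fold-change
#' direction. Zero q-values are floored to half the smallest nonzero
#' q-value in the table to keep scores finite. The result is sorted by
#' descending score, ready for pre-ranked gene-set enrichment.
#'
#' @param records Gene-level DE tibble (collapse first with
#'   [collapse_by_symbol()]).
#' @param log_base Base of the negative log (default 10).
#' @return A tibble `gene_symbol`, `rank_score`, descending by score.
#' @export
signed_rank_scores <- function(records, log_base = 10) {
  validate_de(records)
  q <- records$q_value
  if (any(q == 0)) {
    nz <- q[q > 0]
    if (length(nz) == 0) {
      abort("all q-values are zero; cannot form finite scores",
            class = "spherotax_domain_error")
    }
    q[q == 0] <- min(nz) / 2
  }
  tibble(
    gene_symbol = records$gene_symbol,
    rank_score = -log(q, base = log_base) * sign(records$log2_fold_change)
  ) %>%
    arrange(dplyr::desc(.data$rank_score))
}

#' Fold-change correlation over genes significant in both tables
#'
#' Filters both tables with [filter_de()], collapses to gene level, and
#' reports the Pearson correlation of log2 fold changes over the gene
#' symbols significant in both.
#'
#' @param table_a,table_b DE tibbles.
#' @param fdr_cutoff,min_abs_fold_change Passed to [filter_de()].
#' @return A one-row tibble: `r`, `p_value`, `n_shared`.
#' @export
shared_de_correlation <- function(table_a, table_b, fdr_cutoff = 0.05,
                                  min_abs_fold_change = 2) {
  prep <- function(tb) {
    sig <- filter_de(tb, fdr_cutoff, min_abs_fold_change)
    gene <- suppressWarnings(collapse_by_symbol(sig))
    select(gene, "gene_symbol", "log2_fold_change")
  }
  a <- prep(table_a)
  b <- prep(table_b)
  shared <- dplyr::inner_join(a, b, by = "gene_symbol",
                              suffix = c("_a", "_b"))
  if (nrow(shared) < 3) {
    abort("fewer than 3 genes significant in both tables",
          class = "spherotax_insufficient_overlap")
  }
  ct <- cor.test(shared$log2_fold_change_a, shared$log2_fold_change_b,
                 method = "pearson")
  tibble(r = unname(ct$estimate), p_value = ct$p.value, n_shared = nrow(shared))
}

#' Write / read a pre-ranked gene list (.rnk)
#'
#' The `.rnk` format consumed by pre-ranked enrichment tools: gene symbol
#' TAB score, no header.
#'
#' @param ranked Tibble `gene_symbol`, `rank_score` from
#'   [signed_rank_scores()].
#' @param path Output path.
#' @return `write_rnk()` returns `path` invisibly; `read_rnk()` returns the
#'   ranked tibble.
#' @export
write_rnk <- function(ranked, path) {
  stopifnot(all(c("gene_symbol", "rank_score") %in% names(ranked)))
  readr::write_tsv(ranked[, c("gene_symbol", "rank_score")], path,
                   col_names = FALSE)
  invisible(path)
}

#' @rdname write_rnk
#' @export
read_rnk <- function(path) {
  readr::read_tsv(path, col_names = c("gene_symbol", "rank_score"),
                  col_types = "cd")
}
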