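# End-to-end orchestration: read inputs, translate, build the automaton,
# map, extend, write the three output files, and summarise the run.

#' Assemble and validate a pipeline configuration
#'
#' @param peptide_path Peptide FASTA path.
#' @param genome_path Nucleotide FASTA path (genome, contigs, or selected
#'   features).
#' @param code_table_path Genetic code table file (NCBI toolkit layout); the
#'   bundled `genetic_code_table.txt` is used when `NULL`.
#' @param code_id Integer NCBI genetic code id to select from the table.
#' @param mode Extension mode: `"prokaryote"`, `"eukaryote_signal"`, or
#'   `"fixed"`.
#' @param splice Splice handling in `eukaryote_signal` mode: `"canonical"`,
#'   `"genesplicer"`, or `"none"`.
#' @param genesplicer_path GeneSplicer prediction file (required when
#'   `splice = "genesplicer"`).
#' @param extend_nt Non-negative extension length in nucleotides (required
#'   in `fixed` mode).
#' @param out_prefix Output prefix: files `<prefix>.fasta`, `<prefix>.tsv`,
#'   `<prefix>.gff3` (and `<prefix>.skipped.txt` when peptides are skipped)
#'   are written. `NULL` suppresses file output.
#' @param log_level One of `"debug"`, `"info"`, `"warning"`, `"error"`.
#' @return A `pgmap_config` list.
#' @export
pipeline_config <- function(peptide_path, genome_path,
                            code_table_path = NULL, code_id = 1L,
                            mode = c("prokaryote", "eukaryote_signal", "fixed"),
                            splice = c("canonical", "genesplicer", "none"),
                            genesplicer_path = NULL, extend_nt = NULL,
                            out_prefix = NULL, log_level = "info") {
  mode <- match.arg(mode)
  splice <- match.arg(splice)
  if (is.null(code_table_path)) {
    code_table_path <- system.file("extdata", "genetic_code_table.txt",
                                   package = "pgmap")
  }
  if (mode == "fixed") {
    if (is.null(extend_nt)) abort("fixed mode requires `extend_nt`")
  } else if (!is.null(extend_nt)) {
    abort("`extend_nt` is only meaningful in fixed mode")
  }
  if (mode == "eukaryote_signal" && splice == "genesplicer") {
    if (is.null(genesplicer_path)) {
      abort("splice = \"genesplicer\" requires `genesplicer_path`")
    }
  } else if (!is.null(genesplicer_path)) {
    abort("`genesplicer_path` is only meaningful with splice = \"genesplicer\"")
  }
  structure(
    list(peptide_path = peptide_path, genome_path = genome_path,
         code_table_path = code_table_path, code_id = as.integer(code_id),
         mode = mode, splice = splice, genesplicer_path = genesplicer_path,
         extend_nt = extend_nt, out_prefix = out_prefix,
         log_level = log_level),
    class = "pgmap_config"
  )
}

#' Run the proteogenomic mapping pipeline
#'
#' Reads the peptide and nucleotide FASTA files, selects the genetic code,
#' maps every peptide exactly onto all six reading frames of every record,
#' extends each match into an ePST under the configured mode, and (when an
#' output prefix is configured) writes the ePST FASTA, the detailed TSV
#' report and the GFF3 track. Zero matches is a valid result, not an error.
#'
#' @param config A `pgmap_config` from [pipeline_config()], or arguments to
#'   forward to it (`run_pipeline(peptide_path = ..., ...)`).
#' @param ... Used when `config` is missing: forwarded to
#'   [pipeline_config()].
#' @return A `pgmap_run` object: the run summary (counts, per-record match
#'   table) plus the match, ePST and report tibbles. Use [glance()] for the
#'   one-row summary, [tidy()] for the report rows.
#' @examples
#' peps <- system.file("extdata", "ccv_peptides.fasta", package = "pgmap")
#' epsts <- system.file("extdata", "ccv_epsts.fasta", package = "pgmap")
#' run <- run_pipeline(pipeline_config(peps, epsts, code_id = 1))
#' glance(run)
#' @export
run_pipeline <- function(config, ...) {
  if (missing(config)) config <- pipeline_config(...)
  if (!inherits(config, "pgmap_config")) {
    abort("`config` must come from pipeline_config()")
  }
  old <- options(pgmap.log_level = config$log_level)
  on.exit(options(old), add = TRUE)

  pg_log("info", "reading peptides from ", config$peptide_path)
  peptides <- read_peptide_fasta(config$peptide_path)
  pg_log("info", "reading nucleotide records from ", config$genome_path)
  records <- read_nucleotide_fasta(config$genome_path)
  codes <- parse_code_table(config$code_table_path)
  code <- select_code(codes, config$code_id)
  pg_log("info", sprintf("using genetic code %d (%s)", code$id, code$name))

  matches <- map_peptides(peptides, records, code)
  skipped <- attr(matches, "skipped")
  pg_log("info", sprintf("%d exact match(es) for %d peptide(s)",
                         nrow(matches), length(unique(matches$peptide_id))))

  epsts <- switch(config$mode,
    prokaryote = extend_prokaryotic(matches, records, code),
    eukaryote_signal = {
      sites <- if (config$splice == "genesplicer") {
        parse_genesplicer(config$genesplicer_path)
      } else {
        config$splice
      }
      extend_eukaryotic_signal(matches, records, code, sites)
    },
    fixed = extend_fixed(matches, records, code, config$extend_nt)
  )
  report <- epst_report(epsts, records)

  if (!is.null(config$out_prefix)) {
    write_epst_fasta(epsts, paste0(config$out_prefix, ".fasta"))
    write_epst_tsv(report, paste0(config$out_prefix, ".tsv"))
    write_epst_gff3(epsts, paste0(config$out_prefix, ".gff3"))
    if (nrow(skipped) > 0L) {
      readr::write_tsv(skipped, paste0(config$out_prefix, ".skipped.txt"),
                       progress = FALSE)
    }
    pg_log("info", "wrote ", config$out_prefix, ".{fasta,tsv,gff3}")
  }

  per_record <- dplyr::count(matches, .data$record_id, name = "n_matches")
  structure(
    list(
      n_peptides_in = nrow(peptides) + nrow(skipped),
      n_peptides_skipped = nrow(skipped),
      n_records = nrow(records),
      n_matches = nrow(matches),
      n_peptides_with_match = length(unique(matches$peptide_id)),
      n_epsts = nrow(epsts),
      per_record = per_record,
      matches = matches, epsts = epsts, report = report,
      skipped = skipped, config = config,
      code = code
    ),
    class = "pgmap_run"
  )
}

#' @export
print.pgmap_run <- function(x, ...) {
  cat("<pgmap_run>\n")
  cat(sprintf("  mode: %s | genetic code %d (%s)\n",
              x$config$mode, x$code$id, x$code$name))
  cat(sprintf("  peptides: %d in, %d skipped, %d with >=1 match\n",
              x$n_peptides_in, x$n_peptides_skipped, x$n_peptides_with_match))
  cat(sprintf("  records: %d | exact matches: %d | ePSTs: %d\n",
              x$n_records, x$n_matches, x$n_epsts))
  invisible(x)
}

#' @importFrom generics tidy
#' @export
generics::tidy

#' @importFrom generics glance
#' @export
generics::glance

#' Tidy the per-ePST report of a pipeline run
#'
#' @param x A `pgmap_run`.
#' @param ... Unused.
#' @return The 14-column report tibble (one row per ePST).
#' @method tidy pgmap_run
#' @export
tidy.pgmap_run <- function(x, ...) x$report

#' One-row summary of a pipeline run
#'
#' @param x A `pgmap_run`.
#' @param ... Unused.
#' @return A one-row tibble of run counts.
#' @method glance pgmap_run
#' @export
glance.pgmap_run <- function(x, ...) {
  tibble(
    n_peptides_in = x$n_peptides_in,
    n_peptides_skipped = x$n_peptides_skipped,
    n_records = x$n_records,
    n_matches = x$n_matches,
    n_peptides_with_match = x$n_peptides_with_match,
    n_epsts = x$n_epsts
  )
}

#' Plot ePST spans along their records
#'
#' Draws each ePST as a horizontal segment at its forward-strand
#' coordinates, with the reverse-translated peptide overlaid as a thicker
#' segment, faceted by record and coloured by strand.
#'
#' @param object A `pgmap_run`.
#' @param ... Unused.
#' @return A ggplot object.
#' @method autoplot pgmap_run
#' @export
autoplot.pgmap_run <- function(object, ...) {
  epsts <- object$epsts
  if (nrow(epsts) == 0L) {
    return(ggplot2::ggplot() +
             ggplot2::annotate("text", x = 0, y = 0, label = "no ePSTs") +
             ggplot2::theme_void())
  }
  epsts <- dplyr::mutate(epsts,
    y = stats::ave(seq_len(nrow(epsts)), epsts$record_id, FUN = seq_along))
  ggplot2::ggplot(epsts) +
    ggplot2::geom_segment(ggplot2::aes(
      x = .data$epst_start, xend = .data$epst_end,
      y = .data$y, yend = .data$y, colour = .data$strand),
      linewidth = 1) +
    ggplot2::geom_segment(ggplot2::aes(
      x = .data$nt_start, xend = .data$nt_end,
      y = .data$y, yend = .data$y, colour = .data$strand),
      linewidth = 3) +
    ggplot2::facet_wrap(ggplot2::vars(.data$record_id), scales = "free") +
    ggplot2::labs(x = "position (nt, forward strand)", y = NULL,
                  title = "ePSTs (thin) anchored by mapped peptides (thick)") +
    ggplot2::theme_minimal() +
    ggplot2::theme(axis.text.y = ggplot2::element_blank())
}

#' @importFrom ggplot2 autoplot
#' @export
ggplot2::autoplot

#' @rdname autoplot.pgmap_run
#' @param x A `pgmap_run`.
#' @param y Unused.
#' @export
plot.pgmap_run <- function(x, y, ...) print(autoplot.pgmap_run(x, ...))
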