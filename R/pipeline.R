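#' Run the digestion stage and write its outputs
#'
#' Digests a FASTA input with an enzyme panel, writes the fragment table
#' (TSV), the fragments as FASTA, and the length-class summary (TSV).
#'
#' @param fasta Path to the input FASTA; defaults to the bundled lectin.
#' @param panel Enzyme panel; defaults to [gi_panel()].
#' @param out_dir Output directory (created if needed).
#' @return Invisibly, a list with `digest` (the `tp_digest` tibble) and
#'   `summary` (the length-class tibble).
#' @export
#' @examples
#' res <- run_digest(out_dir = tempfile())
#' res$summary
run_digest <- function(fasta = tp_file("lectin_6tt9.fasta"),
                       panel = gi_panel(),
                       out_dir = "teparypep_out") {
  proteins <- read_fasta(fasta)
  d <- digest(proteins, panel)
  s <- glance(d)
  dir.create(out_dir, showWarnings = FALSE, recursive = TRUE)
  write_digest_tsv(d, file.path(out_dir, "fragments.tsv"))
  frag_records <- tibble(
    id = sprintf("%s_frag%03d", d$parent_id, seq_len(nrow(d))),
    description = sprintf("start=%d end=%d", d$start, d$end),
    sequence = d$sequence
  )
  write_fasta(frag_records, file.path(out_dir, "fragments.fasta"))
  readr::write_tsv(s, file.path(out_dir, "digest_summary.tsv"))
  invisible(list(digest = d, summary = s))
}

#' Run the screening stage and write the annotated peptide report
#'
#' Applies the high-affinity threshold and the candidate-selection triage
#' to an affinity table plus docking results, writing the annotated
#' report as TSV and JSON.
#'
#' @param affinity Path to the affinity TSV; defaults to the bundled
#'   table.
#' @param docking Path to the docking TSV; defaults to the bundled table.
#' @param controls Path to the control-ligand TSV.
#' @param threshold High-affinity cutoff (kcal/mol).
#' @param sites Binding-site residue set.
#' @param out_dir Output directory.
#' @return Invisibly, the `tp_screen` tibble.
#' @export
#' @examples
#' scr <- run_screen(out_dir = tempfile())
#' scr$peptide[scr$candidate]
run_screen <- function(affinity = tp_file("affinity_hpepdock.tsv"),
                       docking = tp_file("docking_pparg.tsv"),
                       controls = tp_file("controls_pparg.tsv"),
                       threshold = -120,
                       sites = pparg_site_set(),
                       out_dir = "teparypep_out") {
  aff <- read_affinity(affinity)
  dock <- read_docking(docking)
  ctrl <- read_controls(controls)
  report <- rank_candidates(aff, dock, sites = sites, controls = ctrl,
                            threshold = threshold)
  dir.create(out_dir, showWarnings = FALSE, recursive = TRUE)
  flat <- as_tibble(report) |>
    mutate(site_contacts = map_chr(.data$site_contacts, paste, collapse = ";"))
  readr::write_tsv(flat, file.path(out_dir, "screen_report.tsv"))
  jsonlite::write_json(flat, file.path(out_dir, "screen_report.json"),
                       auto_unbox = TRUE, digits = NA, pretty = TRUE)
  invisible(report)
}

#' Run the nutrition stage and write the protein-quality report
#'
#' Computes, per sample: Atwater energy from the proximate table, the
#' chemical score with its limiting essential amino acid from the
#' composition table, and (when IVPD values are given) the calculated
#' protein efficiency ratio. The C-PER column is a soft comparative
#' index; see [cper()].
#'
#' @param composition Path to the amino-acid composition TSV.
#' @param proximate Path to the proximate-composition TSV.
#' @param ivpd Path to a TSV with columns `sample_id`, `ivpd_pct`, or
#'   `NULL` to skip C-PER.
#' @param reference Reference amino-acid pattern.
#' @param out_dir Output directory.
#' @return Invisibly, the per-sample quality report tibble.
#' @export
#' @examples
#' run_nutrition(out_dir = tempfile())
run_nutrition <- function(composition = tp_file("aa_composition.tsv"),
                          proximate = tp_file("proximate.tsv"),
                          ivpd = tp_file("ivpd.tsv"),
                          reference = fao_reference(),
                          out_dir = "teparypep_out") {
  prof <- read_aa_composition(composition)
  prox <- read_proximate(proximate)
  cs <- glance(chemical_score(prof, reference))
  report <- prox |>
    select("sample_id", "protein_pct", "fat_pct", "carb_pct", "energy_kcal") |>
    left_join(select(cs, "sample_id", "limiting_item", "score"),
              by = "sample_id") |>
    rename(chemical_score = "score")
  if (!is.null(ivpd)) {
    ivpd_tab <- readr::read_tsv(ivpd, show_col_types = FALSE)
    cp <- cper(prof, ivpd_tab, reference)
    report <- left_join(report,
                        select(cp, "sample_id", "ivpd_pct", "cper"),
                        by = "sample_id")
  }
  dir.create(out_dir, showWarnings = FALSE, recursive = TRUE)
  readr::write_tsv(report, file.path(out_dir, "nutrition_report.tsv"))
  invisible(report)
}

#' Run the whole pipeline on the bundled study inputs
#'
#' One call reproduces every stage with its default configuration:
#' digestion of the bundled lectin, the affinity/docking screen, and the
#' nutrition indices, writing all reports under `out_dir` together with a
#' `provenance.json` recording the panel, threshold, site set and input
#' checksums.
#'
#' @param out_dir Output directory.
#' @param threshold High-affinity cutoff (kcal/mol).
#' @return Invisibly, a list with elements `digest`, `summary`, `screen`,
#'   `nutrition`.
#' @export
#' @examples
#' res <- run_all(out_dir = tempfile())
#' res$summary
run_all <- function(out_dir = "teparypep_out", threshold = -120) {
  dres <- run_digest(out_dir = out_dir)
  scr <- run_screen(threshold = threshold, out_dir = out_dir)
  nut <- run_nutrition(out_dir = out_dir)
  panel <- gi_panel()
  inputs <- c("lectin_6tt9.fasta", "affinity_hpepdock.tsv",
              "docking_pparg.tsv", "controls_pparg.tsv",
              "aa_composition.tsv", "proximate.tsv", "ivpd.tsv")
  provenance <- list(
    panel = list(
      name = attr(panel, "panel_name"),
      rules = lapply(seq_len(nrow(panel)), function(i) list(
        enzyme = panel$enzyme_name[[i]],
        ec = panel$ec_number[[i]],
        p1 = panel$p1[[i]],
        p1prime_exclusions = panel$p1prime_exclusions[[i]]
      ))
    ),
    threshold_kcal_mol = threshold,
    site_set = pparg_site_set(),
    input_md5 = as.list(stats::setNames(
      vapply(inputs, function(f) unname(tools::md5sum(tp_file(f))), character(1)),
      inputs
    ))
  )
  jsonlite::write_json(provenance, file.path(out_dir, "provenance.json"),
                       auto_unbox = TRUE, pretty = TRUE)
  invisible(list(digest = dres$digest, summary = dres$summary,
                 screen = scr, nutrition = nut))
}
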