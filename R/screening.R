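#' The screened antiadipogenic binding-site residues of PPAR-gamma
#'
#' Residues of the PPAR-gamma ligand-binding domain targeted by the
#' docking screen. Residue identifiers are 3-letter code plus sequence
#' number; comparisons are case-insensitive and chains are not modeled.
#'
#' @return Character vector of residue identifiers.
#' @export
#' @examples
#' pparg_site_set()
pparg_site_set <- function() {
  c("Phe264", "His266", "Ile281", "Cys285",
    "Arg288", "Ser289", "Met348", "His449")
}

#' Read a peptide-affinity score table
#'
#' TSV with columns `peptide` and `hpepdock_score` (kcal/mol, more
#' negative = higher affinity). Scores are external docking-server output
#' ingested as data and never recomputed here. The bundled
#' `affinity_hpepdock.tsv` holds the 45 absorbable peptides released from
#' the lectin digest with their published scores.
#'
#' @param path Path to the TSV.
#' @return Tibble with columns `peptide`, `hpepdock_score`, in file order.
#' @export
#' @examples
#' read_affinity(tp_file("affinity_hpepdock.tsv"))
read_affinity <- function(path) {
  if (!file.exists(path)) {
    abort(paste0("affinity file not found: ", path), class = "tp_missing_input")
  }
  tab <- readr::read_tsv(path, show_col_types = FALSE,
                         col_types = readr::cols(
                           peptide = readr::col_character(),
                           hpepdock_score = readr::col_double()
                         ))
  if (nrow(tab) == 0L) {
    abort("no records in affinity table", class = "tp_validation")
  }
  bad <- which(is.na(tab$peptide) | is.na(tab$hpepdock_score))
  if (length(bad) > 0L) {
    abort(paste0("malformed affinity row at line ", bad[1] + 1L),
          class = "tp_validation")
  }
  check_protein_alphabet(tab$peptide, ids = tab$peptide)
  tab
}

#' Keep high-affinity records
#'
#' Retains records whose score is strictly below the threshold (more
#' negative = higher affinity), preserving input order. The default
#' threshold of -120 kcal/mol is the high-affinity cutoff used throughout
#' the pipeline.
#'
#' @param records Tibble from [read_affinity()] (columns `peptide`,
#'   `hpepdock_score`).
#' @param threshold Affinity cutoff in kcal/mol.
#' @return Filtered tibble.
#' @export
#' @examples
#' filter_high_affinity(read_affinity(tp_file("affinity_hpepdock.tsv")))
filter_high_affinity <- function(records, threshold = -120) {
  stopifnot(is.data.frame(records))
  filter(records, .data$hpepdock_score < threshold)
}

#' Fraction of hydrophobic residues in a peptide
#'
#' Hydrophobic set: V, L, I, A, F, W, M, P. Hydrophobicity of screened
#' peptides is linked to bioactivity at lipid-regulating receptors.
#'
#' @param peptide Character vector of peptides.
#' @return Numeric vector in `[0, 1]`.
#' @export
#' @examples
#' hydrophobic_fraction(c("TTPW", "VSVGF"))
hydrophobic_fraction <- function(peptide) {
  check_protein_alphabet(peptide, ids = peptide)
  map_dbl <- function(p) {
    chars <- strsplit(p, "", fixed = TRUE)[[1]]
    mean(chars %in% HYDROPHOBIC_AA)
  }
  vapply(peptide, map_dbl, numeric(1), USE.NAMES = FALSE)
}

#' Intestinal transporter class by peptide length
#'
#' Di- and tripeptides cross the gut epithelium through the PepT1/PepT2
#' proton-dependent oligopeptide transporters; 4-5-mers through
#' SOPT1/SOPT2; single residues use amino-acid transporters; longer
#' peptides have no dedicated carrier.
#'
#' @param peptide Character vector of peptides.
#' @return Character vector with values `"AA_TRANSPORT"`, `"PEPT"`,
#'   `"SOPT"` or `"NONE"`.
#' @export
#' @examples
#' transporter_class(c("PEW", "VSVGF", "EAEAAASAN"))
transporter_class <- function(peptide) {
  check_protein_alphabet(peptide, ids = peptide)
  len <- nchar(peptide)
  dplyr::case_when(
    len == 1L ~ "AA_TRANSPORT",
    len <= 3L ~ "PEPT",
    len <= 5L ~ "SOPT",
    TRUE ~ "NONE"
  )
}

#' Does a peptide contain proline?
#'
#' Proline-containing peptides resist intracellular peptidases, raising
#' the chance of intact absorption.
#'
#' @param peptide Character vector of peptides.
#' @return Logical vector.
#' @export
#' @examples
#' contains_proline(c("TTPW", "ITY"))
contains_proline <- function(peptide) {
  check_protein_alphabet(peptide, ids = peptide)
  str_detect(peptide, "P")
}

# Parse a semicolon-separated contact string into residue identifiers.
parse_contacts <- function(contacts) {
  map(str_split(contacts, ";"), function(x) {
    x <- str_trim(x)
    x[nzchar(x)]
  })
}

#' Read a docking-result table
#'
#' TSV with columns `ligand`, `binding_energy` (kcal/mol, AutoDock-style)
#' and `contacts` (semicolon-separated residue identifiers such as
#' `Cys285`); an optional `hpepdock_score` column is carried through.
#' Energies and contacts are external docking output ingested as data.
#'
#' @param path Path to the TSV; `docking_pparg.tsv` bundles the docking
#'   profiles of the seven high-affinity lectin peptides.
#' @return Tibble with `contacts` as a list-column of character vectors.
#' @export
#' @examples
#' read_docking(tp_file("docking_pparg.tsv"))
read_docking <- function(path) {
  if (!file.exists(path)) {
    abort(paste0("docking file not found: ", path), class = "tp_missing_input")
  }
  tab <- readr::read_tsv(path, show_col_types = FALSE)
  needed <- c("ligand", "binding_energy", "contacts")
  if (!all(needed %in% names(tab))) {
    abort(paste0("docking table needs columns: ", paste(needed, collapse = ", ")),
          class = "tp_validation")
  }
  mutate(tab, contacts = parse_contacts(.data$contacts))
}

#' Read control-ligand docking profiles
#'
#' @param path TSV with columns `name`, `binding_energy`, `contacts`. The
#'   bundled `controls_pparg.tsv` holds the two reference PPAR-gamma
#'   ligands GW9662 (-7.98 kcal/mol) and G3335 (-5.64 kcal/mol).
#' @return Tibble with `contacts` as a list-column.
#' @export
#' @examples
#' read_controls(tp_file("controls_pparg.tsv"))
read_controls <- function(path = tp_file("controls_pparg.tsv")) {
  if (!file.exists(path)) {
    abort(paste0("controls file not found: ", path), class = "tp_missing_input")
  }
  tab <- readr::read_tsv(path, show_col_types = FALSE)
  if (!all(c("name", "binding_energy", "contacts") %in% names(tab))) {
    abort("controls table needs columns: name, binding_energy, contacts",
          class = "tp_validation")
  }
  mutate(tab, contacts = parse_contacts(.data$contacts))
}

#' Intersect docking contacts with a binding-site residue set
#'
#' Adds, for each docking record, the subset of its contacts that fall in
#' the target site (`site_contacts`, case-insensitive residue comparison)
#' and a flag `in_site` marking a non-empty intersection.
#'
#' @param docking Tibble from [read_docking()] (or [read_controls()],
#'   with `name` instead of `ligand`).
#' @param sites Character vector of site residues; defaults to
#'   [pparg_site_set()].
#' @return `docking` with added `site_contacts` (list-column) and
#'   `in_site` columns.
#' @export
#' @examples
#' annotate_docking(read_docking(tp_file("docking_pparg.tsv")))
annotate_docking <- function(docking, sites = pparg_site_set()) {
  stopifnot(is.data.frame(docking), is.list(docking$contacts))
  sites_lc <- tolower(sites)
  docking |>
    mutate(
      site_contacts = map(.data$contacts,
                          function(x) x[tolower(x) %in% sites_lc]),
      in_site = map_lgl(.data$site_contacts, function(x) length(x) > 0L)
    )
}

#' Annotate and select candidate bioactive peptides
#'
#' Combines the affinity screen with the docking triage. Every affinity
#' record is annotated with absorbability features (length, transporter
#' class, hydrophobic fraction, proline flag) and the high-affinity flag
#' (score strictly below `threshold`). Docked peptides additionally carry
#' their binding energy and binding-site contacts. A peptide is flagged a
#' `candidate` when it (1) is high-affinity, (2) contacts at least one
#' binding-site residue, and (3) binds at least as strongly as the weakest
#' control ligand (binding energy less than or equal to the least negative
#' control energy, or `energy_cutoff` if given). This selection rule is a
#' reconstruction of triage against reference ligands and is configurable
#' through `threshold`, `sites` and `energy_cutoff`.
#'
#' @param affinity Tibble from [read_affinity()].
#' @param docking Tibble from [read_docking()]; every docked peptide must
#'   appear in `affinity`.
#' @param sites Binding-site residues; defaults to [pparg_site_set()].
#' @param controls Tibble from [read_controls()]; sets the default energy
#'   cutoff.
#' @param threshold High-affinity cutoff in kcal/mol.
#' @param energy_cutoff Optional explicit binding-energy cutoff
#'   (kcal/mol) overriding the weakest-control rule.
#' @return Tibble of class `tp_screen`, one row per affinity record,
#'   sorted by binding energy ascending (undocked peptides last), with
#'   columns `peptide`, `length`, `transporter_class`,
#'   `hydrophobic_fraction`, `contains_proline`, `hpepdock_score`,
#'   `high_affinity`, `binding_energy`, `site_contacts`, `in_site`,
#'   `candidate`.
#' @export
#' @examples
#' rank_candidates(
#'   read_affinity(tp_file("affinity_hpepdock.tsv")),
#'   read_docking(tp_file("docking_pparg.tsv"))
#' )
rank_candidates <- function(affinity, docking,
                            sites = pparg_site_set(),
                            controls = read_controls(),
                            threshold = -120,
                            energy_cutoff = NULL) {
  stopifnot(is.data.frame(affinity))
  missing <- setdiff(docking$ligand, affinity$peptide)
  if (length(missing) > 0L) {
    abort(paste0("docked peptide(s) absent from affinity table: ",
                 paste(missing, collapse = ", ")),
          class = "tp_validation")
  }
  if (is.null(energy_cutoff)) {
    if (nrow(controls) == 0L) {
      abort("no controls given and no explicit energy_cutoff", class = "tp_validation")
    }
    energy_cutoff <- max(controls$binding_energy)
  }
  dock_ann <- annotate_docking(docking, sites) |>
    select(peptide = "ligand", "binding_energy", "site_contacts", "in_site")
  out <- affinity |>
    mutate(
      length = nchar(.data$peptide),
      transporter_class = transporter_class(.data$peptide),
      hydrophobic_fraction = hydrophobic_fraction(.data$peptide),
      contains_proline = contains_proline(.data$peptide),
      high_affinity = .data$hpepdock_score < threshold
    ) |>
    left_join(dock_ann, by = "peptide") |>
    mutate(
      site_contacts = map(.data$site_contacts, function(x) x %||% character()),
      in_site = !is.na(.data$in_site) & .data$in_site,
      candidate = .data$high_affinity & .data$in_site &
        !is.na(.data$binding_energy) & .data$binding_energy <= energy_cutoff
    ) |>
    arrange(is.na(.data$binding_energy), .data$binding_energy)
  # selection-rule sanity: candidates are always a subset of the
  # high-affinity, in-site peptides
  stopifnot(all(out$high_affinity[out$candidate]),
            all(out$in_site[out$candidate]))
  attr(out, "energy_cutoff") <- energy_cutoff
  attr(out, "threshold") <- threshold
  class(out) <- c("tp_screen", class(out))
  out
}

#' Plot the affinity screen
#'
#' @param object A `tp_screen` tibble from [rank_candidates()].
#' @param ... Unused.
#' @return A ggplot of affinity scores with the high-affinity threshold,
#'   candidates highlighted.
#' @method autoplot tp_screen
#' @export
autoplot.tp_screen <- function(object, ...) {
  thr <- attr(object, "threshold") %||% -120
  df <- as_tibble(object) |>
    arrange(.data$hpepdock_score) |>
    mutate(peptide = factor(.data$peptide, levels = unique(.data$peptide)))
  ggplot2::ggplot(df, ggplot2::aes(x = .data$peptide,
                                   y = .data$hpepdock_score,
                                   colour = .data$candidate)) +
    ggplot2::geom_point() +
    ggplot2::geom_hline(yintercept = thr, linetype = "dashed") +
    ggplot2::scale_colour_manual(values = c(`FALSE` = "grey40",
                                            `TRUE` = "firebrick")) +
    ggplot2::labs(x = NULL, y = "Affinity score (kcal/mol)",
                  colour = "Candidate",
                  title = "Peptide affinity screen",
                  subtitle = paste0("dashed line: high-affinity threshold ",
                                    thr, " kcal/mol")) +
    ggplot2::theme_minimal() +
    ggplot2::theme(axis.text.x = ggplot2::element_text(angle = 90,
                                                       vjust = 0.5, size = 6))
}
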