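#' FAO scoring pattern for children 3 years and older
#'
#' Essential-amino-acid requirements (g/100 g protein) used as the
#' reference pattern for [chemical_score()]. The sulfur and aromatic
#' amino acids are scored as the printed groups `Meth+Cys` and `Phe+Tyr`;
#' groups are atomic and never split into constituent residues.
#'
#' @return A tibble with columns `item` and `requirement`.
#' @export
#' @examples
#' fao_reference()
fao_reference <- function() {
  tibble(
    item = c("His", "Thr", "Meth+Cys", "Val", "Phe+Tyr",
             "Ile", "Leu", "Trp", "Lys"),
    requirement = c(1.6, 2.5, 2.3, 4.0, 4.1, 3.0, 6.1, 0.66, 4.8)
  )
}

#' Read an amino-acid composition table
#'
#' Reads a wide TSV (first column `item`, one column per sample, contents
#' in g/100 g protein) into a long tibble. Repeated rows that are
#' character-identical are deduplicated; repeated items with conflicting
#' values raise an error.
#'
#' @param path Path to the TSV; the bundled `aa_composition.tsv` holds the
#'   profiles of the four tepary-bean samples (RF, CF, RPC, CPC).
#' @return A tibble with columns `sample_id`, `item`, `content`.
#' @export
#' @examples
#' read_aa_composition(tp_file("aa_composition.tsv"))
read_aa_composition <- function(path) {
  if (!file.exists(path)) {
    abort(paste0("composition file not found: ", path), class = "tp_missing_input")
  }
  wide <- readr::read_tsv(path, show_col_types = FALSE)
  if (!"item" %in% names(wide) || ncol(wide) < 2L) {
    abort("composition table needs an 'item' column plus sample columns",
          class = "tp_validation")
  }
  wide <- distinct(wide)
  dup <- wide$item[duplicated(wide$item)]
  if (length(dup) > 0L) {
    abort(paste0("conflicting duplicate rows for item(s): ",
                 paste(unique(dup), collapse = ", ")),
          class = "tp_validation")
  }
  long <- tidyr::pivot_longer(wide, -"item",
                              names_to = "sample_id", values_to = "content")
  if (any(long$content < 0, na.rm = TRUE)) {
    abort("amino-acid contents must be non-negative", class = "tp_validation")
  }
  select(long, "sample_id", "item", "content")
}

# Per-sample ratio table vs a reference pattern; errors when a reference
# item is missing from a sample's profile.
chem_ratios <- function(profile, reference) {
  stopifnot(is.data.frame(profile), is.data.frame(reference))
  profile <- as_tibble(profile)
  if (!"sample_id" %in% names(profile)) profile$sample_id <- "sample"
  for (sid in unique(profile$sample_id)) {
    missing <- setdiff(reference$item,
                       profile$item[profile$sample_id == sid])
    if (length(missing) > 0L) {
      abort(paste0("incomplete profile for '", sid, "': missing item(s) ",
                   paste(missing, collapse = ", ")),
            class = "tp_validation")
    }
  }
  profile |>
    dplyr::inner_join(reference, by = "item") |>
    mutate(
      item = factor(.data$item, levels = reference$item),
      ratio = 100 * .data$content / .data$requirement
    ) |>
    arrange(.data$sample_id, .data$item) |>
    mutate(item = as.character(.data$item))
}

#' FAO chemical score and limiting essential amino acid
#'
#' For each sample, computes `100 * content / requirement` for every item
#' of the reference pattern, identifies the limiting item (minimum ratio;
#' ties broken by reference-pattern order), and reports the score as the
#' minimum ratio rounded half away from zero to the nearest integer.
#' Items without a reference requirement (Asp, Glu, Ser, Gly, Arg, Ala)
#' are ignored.
#'
#' @param profile Long composition tibble ([read_aa_composition()] output)
#'   with columns `sample_id` (optional), `item`, `content`.
#' @param reference Reference pattern; defaults to [fao_reference()].
#' @return An object of class `tp_chemscore`: use [glance()] for the
#'   per-sample summary (`limiting_item`, `score`) and [tidy()] for the
#'   unrounded per-item ratios.
#' @export
#' @examples
#' cs <- chemical_score(read_aa_composition(tp_file("aa_composition.tsv")))
#' glance(cs)
chemical_score <- function(profile, reference = fao_reference()) {
  ratios <- chem_ratios(profile, reference)
  summary <- ratios |>
    group_by(.data$sample_id) |>
    summarise(
      limiting_item = .data$item[which.min(.data$ratio)],
      min_ratio = min(.data$ratio),
      score = round_half_away(min(.data$ratio)),
      .groups = "drop"
    )
  structure(
    list(ratios = ratios, summary = summary, reference = reference),
    class = "tp_chemscore"
  )
}

#' @rdname tidy_teparypep
#' @method tidy tp_chemscore
#' @export
tidy.tp_chemscore <- function(x, ...) x$ratios

#' @rdname tidy_teparypep
#' @method glance tp_chemscore
#' @export
glance.tp_chemscore <- function(x, ...) x$summary

#' @export
print.tp_chemscore <- function(x, ...) {
  cat("<chemical score vs reference pattern>\n")
  print(x$summary)
  invisible(x)
}

#' Plot per-item chemical-score ratios
#'
#' @param object A `tp_chemscore` object.
#' @param ... Unused.
#' @return A ggplot dot chart of ratios per item and sample, with the 100
#'   reference line.
#' @method autoplot tp_chemscore
#' @export
autoplot.tp_chemscore <- function(object, ...) {
  ggplot2::ggplot(
    object$ratios,
    ggplot2::aes(x = .data$item, y = .data$ratio, colour = .data$sample_id)
  ) +
    ggplot2::geom_point(size = 2) +
    ggplot2::geom_hline(yintercept = 100, linetype = "dashed") +
    ggplot2::labs(x = "Essential amino acid (item)",
                  y = "100 x content / requirement",
                  colour = "Sample",
                  title = "Chemical-score ratios vs FAO pattern") +
    ggplot2::theme_minimal() +
    ggplot2::theme(axis.text.x = ggplot2::element_text(angle = 45, hjust = 1))
}

#' Chemical-score ratio for one named item
#'
#' @inheritParams chemical_score
#' @param item Item name, e.g. `"Meth+Cys"`.
#' @return Tibble with columns `sample_id`, `item`, `score` (ratio rounded
#'   to the nearest integer, half away from zero).
#' @export
#' @examples
#' score_for_item(read_aa_composition(tp_file("aa_composition.tsv")), "Meth+Cys")
score_for_item <- function(profile, item, reference = fao_reference()) {
  if (!item %in% reference$item) {
    abort(paste0("unknown reference item: ", item), class = "tp_validation")
  }
  ratios <- chem_ratios(profile, reference)
  ratios |>
    filter(.data$item == !!item) |>
    mutate(score = round_half_away(.data$ratio)) |>
    select("sample_id", "item", "score")
}

#' Atwater energy of a macronutrient composition
#'
#' `4 * protein + 4 * carbohydrate + 9 * fat`, in kcal per 100 g, reported
#' to 2 decimal places. Dietary fiber is not assigned energy.
#'
#' @param protein_pct,carb_pct,fat_pct Macronutrients in g/100 g (dry
#'   basis); vectorized, all non-negative.
#' @return Numeric vector of energies (kcal/100 g).
#' @export
#' @examples
#' atwater_energy(23.46, 66.02, 1.89)
atwater_energy <- function(protein_pct, carb_pct, fat_pct) {
  vals <- c(protein_pct, carb_pct, fat_pct)
  if (any(is.na(vals)) || any(vals < 0)) {
    abort("macronutrient inputs must be non-negative and non-missing",
          class = "tp_validation")
  }
  round_half_away(4 * protein_pct + 4 * carb_pct + 9 * fat_pct, 2)
}

#' Read a proximate-composition table
#'
#' @param path TSV with columns `sample_id`, `protein_pct`, `fat_pct`,
#'   `fiber_pct`, `carb_pct`; the bundled `proximate.tsv` holds the four
#'   tepary-bean samples (fiber not determined for the concentrates).
#' @return A tibble with an added `energy_kcal` column ([atwater_energy()]).
#' @export
#' @examples
#' read_proximate(tp_file("proximate.tsv"))
read_proximate <- function(path) {
  if (!file.exists(path)) {
    abort(paste0("proximate file not found: ", path), class = "tp_missing_input")
  }
  tab <- readr::read_tsv(path, show_col_types = FALSE)
  needed <- c("sample_id", "protein_pct", "fat_pct", "carb_pct")
  if (!all(needed %in% names(tab))) {
    abort(paste0("proximate table needs columns: ", paste(needed, collapse = ", ")),
          class = "tp_validation")
  }
  mutate(tab, energy_kcal = atwater_energy(.data$protein_pct,
                                           .data$carb_pct,
                                           .data$fat_pct))
}

#' In vitro protein digestibility
#'
#' `100 * final / initial`, where `final` is the soluble-protein
#' percentage at the end of the duodenal phase (120 min) and `initial` the
#' percentage before digestion (0 min). Values above 100 are reported with
#' a warning, not clamped.
#'
#' @param final_protein_pct,initial_protein_pct Protein percentages;
#'   vectorized.
#' @return Numeric vector of IVPD percentages.
#' @export
#' @examples
#' ivpd(31.8, 50.0)
ivpd <- function(final_protein_pct, initial_protein_pct) {
  if (any(initial_protein_pct <= 0)) {
    abort("initial protein percentage must be > 0", class = "tp_validation")
  }
  if (any(final_protein_pct < 0)) {
    abort("final protein percentage must be >= 0", class = "tp_validation")
  }
  out <- 100 * final_protein_pct / initial_protein_pct
  if (any(out > 100)) {
    warn("IVPD above 100%: final protein exceeds initial protein")
  }
  out
}

#' Calculated protein efficiency ratio (C-PER)
#'
#' Predicts a rat-bioassay protein efficiency ratio from the
#' essential-amino-acid profile and the in vitro protein digestibility,
#' in the spirit of the AOAC calculated-PER approach (regressions of PER
#' on EAA scores and enzymatic digestibility). As the exact published
#' regression coefficients vary between method revisions, this package
#' uses a transparent reconstruction:
#' \deqn{CPER = 2.5 \times \frac{EAAI}{100} \times \frac{IVPD}{90}}
#' where EAAI is the essential-amino-acid index (geometric mean of the
#' per-item ratios vs the reference pattern, each capped at 100), 2.5 is
#' the PER of the casein reference protein and 90 its typical in vitro
#' digestibility. The prediction is linear, hence monotone non-decreasing,
#' in IVPD. Treat results as a soft, comparative index; the equation is
#' recorded in the `equation` attribute of the output.
#'
#' @inheritParams chemical_score
#' @param ivpd_pct Either a single IVPD percentage (recycled across
#'   samples) or a data frame with columns `sample_id`, `ivpd_pct`. Must
#'   lie in (0, 120].
#' @return Tibble with columns `sample_id`, `ivpd_pct`, `eaa_index`,
#'   `cper`.
#' @export
#' @examples
#' prof <- read_aa_composition(tp_file("aa_composition.tsv"))
#' cper(prof, readr::read_tsv(tp_file("ivpd.tsv"), show_col_types = FALSE))
cper <- function(profile, ivpd_pct, reference = fao_reference()) {
  ratios <- chem_ratios(profile, reference)
  eaai <- ratios |>
    group_by(.data$sample_id) |>
    summarise(eaa_index = exp(mean(log(pmin(.data$ratio, 100)))),
              .groups = "drop")
  if (is.data.frame(ivpd_pct)) {
    if (!all(c("sample_id", "ivpd_pct") %in% names(ivpd_pct))) {
      abort("ivpd_pct data frame needs columns sample_id, ivpd_pct",
            class = "tp_validation")
    }
    out <- dplyr::inner_join(eaai, ivpd_pct, by = "sample_id")
  } else {
    stopifnot(is.numeric(ivpd_pct), length(ivpd_pct) == 1L)
    out <- mutate(eaai, ivpd_pct = ivpd_pct)
  }
  if (any(out$ivpd_pct <= 0 | out$ivpd_pct > 120)) {
    abort("ivpd_pct must lie in (0, 120]", class = "tp_validation")
  }
  out <- out |>
    mutate(cper = 2.5 * (.data$eaa_index / 100) * (.data$ivpd_pct / 90)) |>
    select("sample_id", "ivpd_pct", "eaa_index", "cper")
  attr(out, "equation") <-
    "cper = 2.5 * (eaa_index / 100) * (ivpd_pct / 90); eaa_index = geometric mean of min(ratio, 100) over the reference items"
  out
}
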