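#' Generate random protein records
#'
#' Draws sequences i.i.d. from `residue_freqs` (uniform over the 20
#' canonical residues by default). Output is a pure function of
#' `(seed, n, length, residue_freqs)`; the caller's random state is left
#' untouched.
#'
#' @param n Number of records.
#' @param length Sequence length (single value or vector of length `n`).
#' @param seed Integer seed.
#' @param residue_freqs Optional named numeric vector of residue
#'   probabilities over the canonical alphabet; must sum to 1.
#' @return Tibble of protein records (`id`, `description`, `sequence`).
#' @export
#' @examples
#' random_protein(3, 60, seed = 1)
random_protein <- function(n = 1L, length = 100L, seed = 1L,
                           residue_freqs = NULL) {
  stopifnot(n >= 1L, all(length >= 1L))
  if (is.null(residue_freqs)) {
    residue_freqs <- stats::setNames(rep(1 / 20, 20), AA_ALPHABET)
  }
  if (!setequal(names(residue_freqs), AA_ALPHABET) ||
      any(residue_freqs < 0) ||
      abs(sum(residue_freqs) - 1) > 1e-9) {
    abort("residue_freqs must be a probability vector over the 20 canonical residues",
          class = "tp_validation")
  }
  residue_freqs <- residue_freqs[AA_ALPHABET]
  lens <- rep_len(length, n)
  with_seed(seed, {
    seqs <- vapply(lens, function(L) {
      paste(sample(AA_ALPHABET, L, replace = TRUE, prob = residue_freqs),
            collapse = "")
    }, character(1))
    tibble(
      id = sprintf("synth_%04d", seq_len(n)),
      description = sprintf("synthetic random protein (seed %d)", as.integer(seed)),
      sequence = seqs
    )
  })
}

#' Reference digestion oracle (naive per-bond scan)
#'
#' Independent re-statement of the cleavage semantics used only to
#' cross-check the digestion engine in tests: walk the sequence bond by
#' bond and cut whenever the residue before the bond is in `cut_after`
#' and the residue after it is not in `exclusions`.
#'
#' @param sequence Protein sequence string.
#' @param cut_after Residues cut after (union P1 set).
#' @param exclusions Residues blocking the cut when immediately after the
#'   bond.
#' @return Character vector of fragments, in order.
#' @export
#' @examples
#' oracle_digest("AKA", "K")
oracle_digest <- function(sequence, cut_after, exclusions = character()) {
  check_protein_alphabet(sequence)
  chars <- strsplit(sequence, "", fixed = TRUE)[[1]]
  frags <- character()
  current <- ""
  for (i in seq_along(chars)) {
    current <- paste0(current, chars[i])
    is_last <- i == length(chars)
    cut_here <- !is_last &&
      chars[i] %in% cut_after &&
      !(chars[i + 1] %in% exclusions)
    if (cut_here || is_last) {
      frags <- c(frags, current)
      current <- ""
    }
  }
  frags
}

#' Synthetic amino-acid profile with a planted limiting item
#'
#' Builds a composition whose ratio for `limiting_item` equals
#' `target_score` exactly (before rounding) while every other reference
#' item's ratio exceeds it by at least 10 points, so [chemical_score()]
#' must recover the planted item and score.
#'
#' @param seed Integer seed.
#' @param limiting_item Reference item to plant as limiting.
#' @param target_score Planted score (ratio of the limiting item).
#' @param reference Reference pattern; defaults to [fao_reference()].
#' @return Long profile tibble (`sample_id`, `item`, `content`).
#' @export
#' @examples
#' glance(chemical_score(synthetic_profile(7, "Meth+Cys", 72)))
synthetic_profile <- function(seed, limiting_item, target_score,
                              reference = fao_reference()) {
  if (!limiting_item %in% reference$item) {
    abort(paste0("unknown reference item: ", limiting_item),
          class = "tp_validation")
  }
  stopifnot(target_score > 0)
  with_seed(seed, {
    ratio <- ifelse(
      reference$item == limiting_item,
      target_score,
      target_score + 10 + stats::runif(nrow(reference), 0, 100)
    )
    tibble(
      sample_id = sprintf("planted_%s_%d", limiting_item, as.integer(seed)),
      item = reference$item,
      content = ratio * reference$requirement / 100
    )
  })
}

#' Synthetic affinity table with a planted sub-threshold count
#'
#' Generates `n` peptide affinity records of which exactly `k_below` have
#' scores strictly below `threshold`, so [filter_high_affinity()] must
#' return exactly those. Peptides are drawn from real digests of random
#' proteins (via [random_protein()] and [digest()]) so their length
#' distribution is realistic; scores are then planted around the
#' threshold and shuffled.
#'
#' @param seed Integer seed.
#' @param n Number of records.
#' @param k_below Number of records strictly below `threshold`.
#' @param threshold Affinity cutoff (kcal/mol).
#' @return Tibble with columns `peptide`, `hpepdock_score`, `planted_below`.
#' @export
#' @examples
#' synthetic_affinity(3, 45, 7)
synthetic_affinity <- function(seed, n, k_below, threshold = -120) {
  stopifnot(n >= 0L, k_below >= 0L, k_below <= n)
  with_seed(seed, {
    peptides <- character()
    batch <- 0L
    while (length(peptides) < n) {
      batch <- batch + 1L
      prot <- random_protein(5L, 80L, seed = as.integer(seed) * 1000L + batch)
      peptides <- c(peptides, fragment_multiset(digest(prot), 2L, 5L))
    }
    peptides <- peptides[seq_len(n)]
    below <- threshold - stats::runif(n, 0.5, 40)
    above <- threshold + stats::runif(n, 0.5, 60)
    planted <- sample(c(rep(TRUE, k_below), rep(FALSE, n - k_below)))
    tibble(
      peptide = peptides,
      hpepdock_score = ifelse(planted, below, above),
      planted_below = planted
    )
  })
}

#' Synthetic docking table with one planted candidate
#'
#' Builds docking records for the given peptides in which exactly one
#' peptide (`planted`) contacts the binding site with a binding energy at
#' or below `energy_cutoff`, while every other record fails the site
#' clause or the energy clause, so [rank_candidates()] must flag exactly
#' the planted peptide (provided it is high-affinity in the accompanying
#' affinity table).
#'
#' @param seed Integer seed.
#' @param peptides Character vector of docked peptides.
#' @param planted The one peptide to plant as a passing candidate.
#' @param sites Binding-site residues; defaults to [pparg_site_set()].
#' @param energy_cutoff Binding-energy cutoff (kcal/mol).
#' @return Docking tibble (`ligand`, `binding_energy`, `contacts`
#'   list-column, `planted_candidate`).
#' @export
#' @examples
#' synthetic_docking(4, c("TTPW", "ITY", "TSF"), planted = "ITY")
synthetic_docking <- function(seed, peptides, planted,
                              sites = pparg_site_set(),
                              energy_cutoff = -5.64) {
  stopifnot(planted %in% peptides)
  off_site <- c("Ser342", "Gly284", "Glu291", "Tyr473", "Lys301")
  with_seed(seed, {
    is_planted <- peptides == planted
    # non-planted records fail exactly one clause at random:
    # either no site contact, or a too-weak binding energy
    fail_energy <- stats::runif(length(peptides)) < 0.5
    energy <- ifelse(
      is_planted, energy_cutoff - stats::runif(length(peptides), 0.1, 3),
      ifelse(fail_energy,
             energy_cutoff + stats::runif(length(peptides), 0.5, 3),
             energy_cutoff - stats::runif(length(peptides), 0.1, 3))
    )
    contacts <- lapply(seq_along(peptides), function(i) {
      if (is_planted[i] || !fail_energy[i]) {
        if (is_planted[i]) {
          c(sample(sites, 1), sample(off_site, 1))
        } else {
          # fails the site clause instead
          sample(off_site, 2)
        }
      } else {
        # fails the energy clause; may still sit in the site
        c(sample(sites, 1), sample(off_site, 1))
      }
    })
    # records that fail the energy clause keep site contacts; records that
    # pass the energy clause must miss the site (handled above)
    tibble(
      ligand = peptides,
      binding_energy = energy,
      contacts = contacts,
      planted_candidate = is_planted
    )
  })
}
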