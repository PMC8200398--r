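#' Locate cleavage sites for a panel on one sequence
#'
#' Returns the 0-based boundary indices at which the concerted panel cuts:
#' boundary `b` (strictly between 0 and `nchar(sequence)`) is a site when
#' some rule's P1 set contains the residue at position `b` (1-based) and
#' that rule's P1' exclusions do not contain the residue at `b + 1`. A P1
#' residue at the C-terminus produces no site (no empty fragment).
#'
#' @param sequence A single protein sequence string.
#' @param panel A `tp_panel`, e.g. [gi_panel()].
#' @return Sorted integer vector of cut positions (possibly empty).
#' @export
#' @examples
#' compile_sites("AKA", gi_panel())
compile_sites <- function(sequence, panel) {
  stopifnot(is.character(sequence), length(sequence) == 1L)
  check_protein_alphabet(sequence)
  chars <- strsplit(sequence, "", fixed = TRUE)[[1]]
  n <- length(chars)
  if (n < 2L) return(integer())
  cut <- rep(FALSE, n - 1L)
  for (i in seq_len(nrow(panel))) {
    p1_hit <- chars[seq_len(n - 1L)] %in% panel$p1[[i]]
    blocked <- chars[2:n] %in% panel$p1prime_exclusions[[i]]
    cut <- cut | (p1_hit & !blocked)
  }
  which(cut)
}

#' Concerted in silico digestion
#'
#' Digests each record in `proteins` with the panel acting concertedly and
#' exhaustively: fragments are the maximal substrings between consecutive
#' cut sites, so they partition the parent and contain no internal
#' cut-eligible bond. Duplicate peptides are retained with multiplicity.
#'
#' @param proteins A data frame of protein records ([read_fasta()] output)
#'   with columns `id` and `sequence`.
#' @param panel A `tp_panel`; defaults to the gastrointestinal panel.
#' @return A tibble of class `tp_digest` with columns `parent_id`, `start`
#'   (0-based inclusive), `end` (0-based exclusive), `length`, `sequence`,
#'   in positional order, plus a `panel_name` attribute.
#' @export
#' @examples
#' d <- digest(lectin_record())
#' nrow(d)
digest <- function(proteins, panel = gi_panel()) {
  stopifnot(is.data.frame(proteins))
  if (nrow(proteins) == 0L) {
    abort("no protein records to digest", class = "tp_validation")
  }
  check_protein_alphabet(proteins$sequence, ids = proteins$id)
  frags <- pmap(
    list(proteins$id, proteins$sequence),
    function(id, seqstr) {
      sites <- compile_sites(seqstr, panel)
      bounds <- c(0L, sites, nchar(seqstr))
      start <- bounds[-length(bounds)]
      end <- bounds[-1]
      tibble(
        parent_id = id,
        start = start,
        end = end,
        length = end - start,
        sequence = substring(seqstr, start + 1L, end)
      )
    }
  )
  out <- bind_rows(frags)
  attr(out, "panel_name") <- attr(panel, "panel_name") %||% "custom"
  class(out) <- c("tp_digest", class(out))
  out
}

#' Summarise a digest by absorbability-relevant length classes
#'
#' Counts fragments that are free amino acids (length 1), absorbable
#' peptides (length 2-5, the PepT/SOPT transporter range) and longer
#' peptides (> 5), with percentages rounded half away from zero to 2
#' decimal places.
#'
#' @param result A `tp_digest` tibble (or any data frame with a `length`
#'   column).
#' @return A one-row tibble: `n_free`, `n_2_5`, `n_gt5`, `n_total`,
#'   `pct_free`, `pct_2_5`, `pct_gt5`.
#' @export
#' @examples
#' classify_lengths(digest(lectin_record()))
classify_lengths <- function(result) {
  stopifnot(is.data.frame(result))
  if (nrow(result) == 0L) {
    abort("nothing to classify: digest has no fragments", class = "tp_validation")
  }
  len <- result$length
  n <- length(len)
  counts <- c(sum(len == 1L), sum(len >= 2L & len <= 5L), sum(len > 5L))
  pct <- round_half_away(100 * counts / n, 2)
  tibble(
    n_free = counts[1], n_2_5 = counts[2], n_gt5 = counts[3], n_total = n,
    pct_free = pct[1], pct_2_5 = pct[2], pct_gt5 = pct[3]
  )
}

#' Extract the fragment multiset in a length window
#'
#' @param result A `tp_digest` tibble.
#' @param min_len,max_len Inclusive length bounds; the default window 2-5
#'   selects the transporter-absorbable peptides passed on to screening.
#' @return Character vector of peptides in positional order, duplicates
#'   retained.
#' @export
#' @examples
#' fragment_multiset(digest(lectin_record()))
fragment_multiset <- function(result, min_len = 2L, max_len = 5L) {
  stopifnot(is.data.frame(result))
  if (!(min_len >= 1L && min_len <= max_len)) {
    abort("need 1 <= min_len <= max_len", class = "tp_validation")
  }
  result$sequence[result$length >= min_len & result$length <= max_len]
}

#' Write digest fragments as TSV
#'
#' @param result A `tp_digest` tibble.
#' @param path Output path.
#' @return `path`, invisibly.
#' @export
write_digest_tsv <- function(result, path) {
  readr::write_tsv(as_tibble(result), path)
  invisible(path)
}

#' @rdname tidy_teparypep
#' @method tidy tp_digest
#' @export
tidy.tp_digest <- function(x, ...) {
  as_tibble(x)
}

#' @rdname tidy_teparypep
#' @method glance tp_digest
#' @export
glance.tp_digest <- function(x, ...) {
  mutate(classify_lengths(x),
         panel = attr(x, "panel_name") %||% NA_character_,
         .before = 1)
}

#' Plot the length-class distribution of a digest
#'
#' @param object A `tp_digest` tibble.
#' @param ... Unused.
#' @return A ggplot bar chart of fragment counts per length class.
#' @method autoplot tp_digest
#' @export
autoplot.tp_digest <- function(object, ...) {
  s <- classify_lengths(object)
  df <- tibble(
    class = factor(c("1 (free AA)", "2-5 (absorbable)", ">5"),
                   levels = c("1 (free AA)", "2-5 (absorbable)", ">5")),
    n = c(s$n_free, s$n_2_5, s$n_gt5),
    pct = c(s$pct_free, s$pct_2_5, s$pct_gt5)
  )
  ggplot2::ggplot(df, ggplot2::aes(x = .data$class, y = .data$n)) +
    ggplot2::geom_col(fill = "steelblue") +
    ggplot2::geom_text(ggplot2::aes(label = paste0(.data$pct, "%")),
                       vjust = -0.4, size = 3.2) +
    ggplot2::labs(
      x = "Peptide length class", y = "Number of peptides",
      title = "In silico digest: fragment length distribution"
    ) +
    ggplot2::theme_minimal()
}
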