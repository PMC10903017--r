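# Synthetic stand-in reference sequences.
#
# The original FDC1/PSC1/PSD1 sequences live in the source study's
# supplementary material and are not redistributed here. These builders
# construct a deterministic synthetic trio with the same documented
# relationships, so that the whole pipeline (consensus derivation, alignment
# scoring, key-residue mapping, gene design) can be demonstrated and checked
# end-to-end on sequences with known ground truth:
#
#   * a 503-residue reference enzyme ("FDC1_syn") carrying the catalytic
#     positions I189, Q192, I330, F397, I398;
#   * a 502-residue consensus design ("PSC1_syn") that differs from the
#     reference by 114 residues (113 substitutions + 1 deletion) and
#     conserves all five catalytic positions;
#   * a 503-residue second design ("PSD1_syn") that differs by 223 residues
#     from the reference and 230 from the first design, with the catalytic
#     phenylalanine at 397 replaced by tyrosine and the isoleucine at 398 by
#     threonine.
#
# Everything is reproducible from fixed internal seeds; no external data.

REF_SEED <- 48109L

#' Synthetic reference enzyme trio (FDC1/PSC1/PSD1 stand-ins)
#'
#' Deterministically constructs three related synthetic proteins with known
#' ground-truth relationships (see the package vignette): a 503-aa reference
#' decarboxylase stand-in, a 502-aa consensus design differing from it by 114
#' residues and conserving the five key catalytic positions, and a 503-aa
#' divergent design differing by 223/230 residues from reference/consensus
#' with substitutions F397Y and I398T. These are labelled synthetic: they
#' share no sequence content with the real enzymes, only the documented
#' relational structure.
#'
#' @return A list with `fdc1`, `psc1`, `psd1` (each a `protein_seq`),
#'   `key_positions` (1-based positions in the reference) and
#'   `key_residues` (the reference residues at those positions).
#' @examples
#' refs <- synthetic_fdc_references()
#' nchar(refs$psc1$residues)  # 502
#' @export
synthetic_fdc_references <- function() {
  L <- 503L
  kp <- c(189L, 192L, 330L, 397L, 398L)
  kr <- c("I", "Q", "I", "F", "I")
  del_pos <- 480L
  protected <- sort(unique(c(1:5, 499:503, 470:490, kp)))
  eligible <- setdiff(6:498, protected)
  with_seed(REF_SEED, {
    fdc <- sample(AA_LETTERS, L, replace = TRUE)
    fdc[kp] <- kr
    s1 <- sort(sample(eligible, 113L))
    overlap <- sort(sample(s1, 107L))
    fresh <- sort(sample(setdiff(eligible, s1), 114L))
    psc_full <- fdc
    for (s in s1)
      psc_full[s] <- sample(setdiff(AA_LETTERS, fdc[s]), 1L)
    psd <- fdc
    for (s in overlap)
      psd[s] <- sample(setdiff(AA_LETTERS, c(fdc[s], psc_full[s])), 1L)
    for (s in fresh)
      psd[s] <- sample(setdiff(AA_LETTERS, fdc[s]), 1L)
    psd[397L] <- "Y"
    psd[398L] <- "T"
    list(
      fdc1 = protein_sequence("FDC1_syn", paste0(fdc, collapse = ""),
                              "synthetic 503-aa reference decarboxylase"),
      psc1 = protein_sequence("PSC1_syn",
                              paste0(psc_full[-del_pos], collapse = ""),
                              "synthetic 502-aa consensus design"),
      psd1 = protein_sequence("PSD1_syn", paste0(psd, collapse = ""),
                              "synthetic 503-aa divergent design"),
      key_positions = kp, key_residues = kr,
      psc1_full = paste0(psc_full, collapse = ""),
      deleted_position = del_pos)
  })
}

#' Synthetic high-identity homolog family (stand-in for the >60% tier)
#'
#' Builds an 8-member aligned family around the synthetic reference trio: the
#' reference enzyme stand-in plus seven homologs derived from the consensus
#' target, each with a small number of per-column mutations (at most two
#' mutated members per column, so the design target always holds the column
#' plurality) and a gap-majority column at the consensus deletion site. By
#' construction, [derive_consensus()] on this family under the default policy
#' returns exactly the 502-aa synthetic consensus design.
#'
#' @param seed Seed for the per-column mutation pattern (fixture default 7).
#' @return An `aligned_family` of 8 members x 503 columns, with
#'   `query_id = "FDC1_syn"`.
#' @examples
#' fam <- synthetic_fdc_family()
#' length(fam$members)
#' @export
synthetic_fdc_family <- function(seed = 7L) {
  refs <- synthetic_fdc_references()
  L <- nchar(refs$psc1_full)
  target <- chars(refs$psc1_full)
  del_pos <- refs$deleted_position
  n_derived <- 7L
  with_seed(seed, {
    mat <- matrix(rep(target, n_derived), nrow = n_derived, byrow = TRUE)
    for (j in seq_len(L)) {
      if (j == del_pos) next
      k <- sample(0:2, 1L, prob = c(0.35, 0.40, 0.25))
      if (k > 0L) {
        rows <- sample(n_derived, k)
        for (r in rows)
          mat[r, j] <- sample(setdiff(AA_LETTERS, target[j]), 1L)
      }
    }
    gap_rows <- sample(n_derived, 5L)
    mat[gap_rows, del_pos] <- GAP_CHAR
    members <- c(refs$fdc1$residues,
                 apply(mat, 1L, paste0, collapse = ""))
    names(members) <- c("FDC1_syn", sprintf("fam60_%d", seq_len(n_derived)))
    aligned_family(members, query_id = "FDC1_syn",
                   source_format = "aligned-fasta")
  })
}
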