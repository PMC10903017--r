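# Rule-based "wholesale" consensus derivation: per alignment column, take the
# most frequent character; break residue ties deterministically or at random;
# delete columns where the gap wins outright; fall back to a polar uncharged
# residue (N, then Q) for fully occupied columns with no plurality, and to
# alanine for gap-containing columns with no plurality. Every column's choice
# is recorded with the rule that produced it.

#' Consensus derivation policy
#'
#' The full rule set governing per-column residue choice.
#'
#' @param tie_break How to resolve ties among equally frequent residues:
#'   `"alphabetical"` (deterministic, the default) or `"seeded-random"`
#'   (a seeded draw among the tied set, honoring an "either may be chosen"
#'   convention reproducibly).
#' @param polar_fallback Ordered residue preference for fully occupied
#'   columns with no plurality winner; default asparagine then glutamine,
#'   keeping the designed protein's charge neutral.
#' @param gap_rule Gap-deletion semantics. `"plurality-gap-deletes"` (default)
#'   deletes a column when the gap is the unique most frequent character;
#'   `"majority-gap-deletes"` requires the gap to hold a strict majority.
#' @param filler Residue inserted at gap-containing columns with no plurality
#'   winner; default alanine, whose small volume minimally perturbs folding.
#' @param symbol_map A [symbol_map()] used when expanding a pre-computed
#'   consensus row.
#' @param seed Integer seed for `"seeded-random"` tie-breaking.
#' @return An object of class `consensus_policy`.
#' @export
consensus_policy <- function(tie_break = c("alphabetical", "seeded-random"),
                             polar_fallback = c("N", "Q"),
                             gap_rule = c("plurality-gap-deletes",
                                          "majority-gap-deletes"),
                             filler = "A",
                             symbol_map = default_symbol_map(),
                             seed = 1L) {
  tie_break <- match.arg(tie_break)
  gap_rule <- match.arg(gap_rule)
  polar_fallback <- toupper(polar_fallback)
  filler <- toupper(filler)
  if (!all(polar_fallback %in% AA_LETTERS) || length(polar_fallback) < 1L)
    stop_input("'polar_fallback' must be canonical residues")
  if (!filler %in% AA_LETTERS || length(filler) != 1L)
    stop_input("'filler' must be a single canonical residue")
  structure(list(tie_break = tie_break, polar_fallback = polar_fallback,
                 gap_rule = gap_rule, filler = filler,
                 symbol_map = symbol_map, seed = as.integer(seed)),
            class = "consensus_policy")
}

#' Character counts in one alignment column
#'
#' @param family An `aligned_family`.
#' @param index 1-based column index.
#' @return Named integer vector of counts over residues (and `-` for gaps)
#'   present in the column; counts sum to the number of members.
#' @export
column_counts <- function(family, index) {
  stopifnot(inherits(family, "aligned_family"))
  index <- as.integer(index)
  if (index < 1L || index > alignment_ncol(family))
    stop_bounds("column index ", index, " outside 1..", alignment_ncol(family))
  col <- substr(family$members, index, index)
  tab <- table(col)
  stats::setNames(as.integer(tab), names(tab))
}

#' Decide the consensus action for one column
#'
#' Applies the consensus rule cascade to a column's character counts:
#' \enumerate{
#'   \item gap is the winning character (per `gap_rule`) -> delete the column
#'     (`gap_delete`);
#'   \item a unique most frequent residue exists -> that residue
#'     (`plurality`, or `gap_rescue` when gaps are present but outnumbered);
#'   \item two or more residues tie for the plurality -> `tie_break` selects
#'     among the tied set (`tie`);
#'   \item every character occurs once (no plurality): with gaps present the
#'     filler residue is used (`alanine_filler`); without gaps, the first
#'     applicable residue of `polar_fallback` (`polar_fallback`).
#' }
#'
#' @param counts Named integer vector (residues and optionally `-`).
#' @param policy A [consensus_policy()].
#' @param tie_rng Optional function(k) returning an index in 1..k, used for
#'   seeded-random tie-breaking; supplied by [derive_consensus()].
#' @return A list of class `column_decision`: `action` (`"residue"` or
#'   `"delete"`), `residue` (or `NA`), `rule`, `counts`.
#' @export
decide_column <- function(counts, policy = consensus_policy(),
                          tie_rng = NULL) {
  if (length(counts) == 0L || sum(counts) == 0L)
    stop_input("column counts are empty")
  bad <- setdiff(names(counts), c(AA_LETTERS, "X", GAP_CHAR))
  if (length(bad))
    stop_alphabet("illegal character '", bad[1L], "' in column counts")
  counts <- counts[counts > 0L]
  m <- max(counts)
  winners <- names(counts)[counts == m]
  gaps_present <- GAP_CHAR %in% names(counts)
  gap_wins <- switch(policy$gap_rule,
    "plurality-gap-deletes" = identical(winners, GAP_CHAR),
    "majority-gap-deletes" = gaps_present &&
      counts[[GAP_CHAR]] * 2L > sum(counts))
  decision <- function(action, residue, rule)
    structure(list(action = action, residue = residue, rule = rule,
                   counts = counts), class = "column_decision")
  if (gap_wins) return(decision("delete", NA_character_, "gap_delete"))
  res_winners <- setdiff(winners, GAP_CHAR)
  if (m == 1L && length(counts) > 1L) {
    # no plurality at all: every character occurs exactly once
    if (gaps_present)
      return(decision("residue", policy$filler, "alanine_filler"))
    pref <- policy$polar_fallback
    hit <- pref[pref %in% names(counts)]
    residue <- if (length(hit)) hit[1L] else pref[1L]
    return(decision("residue", residue, "polar_fallback"))
  }
  if (length(res_winners) == 1L) {
    rule <- if (gaps_present) "gap_rescue" else "plurality"
    return(decision("residue", res_winners, rule))
  }
  # >= 2 residues tied for the plurality
  res_winners <- sort(res_winners)
  pick <- if (policy$tie_break == "alphabetical" || is.null(tie_rng)) 1L
          else tie_rng(length(res_winners))
  decision("residue", res_winners[pick], "tie")
}

#' Derive a consensus protein from an aligned family
#'
#' Applies [decide_column()] to every alignment column in order and
#' concatenates the retained residues. The result carries one
#' decision record per column (1-based indices, matching residue-numbering
#' conventions such as "F397") and a snapshot of the policy.
#'
#' @param family An `aligned_family`.
#' @param policy A [consensus_policy()].
#' @param id Identifier given to the consensus sequence.
#' @return An object of class `consensus_result` with fields `consensus`
#'   (a `protein_seq`), `decisions` (data.frame: column, action, residue,
#'   rule, counts), `policy`.
#' @examples
#' fam <- aligned_family(c(a = "MKT", b = "MKT", c = "MRT"))
#' derive_consensus(fam)$consensus$residues
#' @export
derive_consensus <- function(family, policy = consensus_policy(),
                             id = "consensus") {
  stopifnot(inherits(family, "aligned_family"))
  ncol <- alignment_ncol(family)
  # character matrix: members x columns
  mat <- do.call(rbind, strsplit(unname(family$members), "", fixed = TRUE))
  run <- function() {
    tie_rng <- if (policy$tie_break == "seeded-random")
      function(k) sample.int(k, 1L) else NULL
    decs <- vector("list", ncol)
    for (j in seq_len(ncol)) {
      tab <- table(mat[, j])
      counts <- stats::setNames(as.integer(tab), names(tab))
      decs[[j]] <- tryCatch(
        decide_column(counts, policy, tie_rng = tie_rng),
        error = function(e)
          stop_input("column ", j, ": ", conditionMessage(e)))
    }
    decs
  }
  decs <- if (policy$tie_break == "seeded-random")
    with_seed(policy$seed, run()) else run()
  residues <- vapply(decs, function(d)
    if (d$action == "residue") d$residue else "", "")
  if (!any(nzchar(residues)))
    cz_stop("consenzyme_degenerate_error",
            "every alignment column was gap-deleted; the consensus is empty")
  decisions <- data.frame(
    column = seq_len(ncol),
    action = vapply(decs, `[[`, "", "action"),
    residue = vapply(decs, function(d)
      if (is.na(d$residue)) "" else d$residue, ""),
    rule = vapply(decs, `[[`, "", "rule"),
    counts = vapply(decs, function(d)
      paste0(names(d$counts), ":", d$counts, collapse = ","), ""),
    stringsAsFactors = FALSE)
  out <- structure(list(
    consensus = protein_sequence(id, paste0(residues, collapse = "")),
    decisions = decisions, policy = policy), class = "consensus_result")
  stopifnot(nchar(out$consensus$residues) ==
              sum(decisions$action == "residue"))
  out
}

#' @export
print.consensus_result <- function(x, ...) {
  cat(sprintf("<consensus_result> %s: %d residues from %d columns\n",
              x$consensus$id, nchar(x$consensus$residues),
              nrow(x$decisions)))
  cat("  rules applied:\n")
  print(table(x$decisions$rule))
  invisible(x)
}

#' @export
summary.consensus_result <- function(object, ...) {
  cat(sprintf("Consensus '%s': %d aa (from %d alignment columns, %d deleted)\n",
              object$consensus$id, nchar(object$consensus$residues),
              nrow(object$decisions),
              sum(object$decisions$action == "delete")))
  print(table(rule = object$decisions$rule))
  invisible(object)
}

#' Write the per-column decision table as TSV
#'
#' @param result A `consensus_result`.
#' @param path Output path.
#' @return `path`, invisibly.
#' @export
write_decision_table <- function(result, path) {
  stopifnot(inherits(result, "consensus_result"))
  utils::write.table(result$decisions, path, sep = "\t", quote = FALSE,
                     row.names = FALSE)
  invisible(path)
}

#' Re-derive a consensus from a pre-computed MultAlin consensus row
#'
#' When only the alignment program's consensus row is available (not the raw
#' members), class symbols are first expanded through the policy's symbol map
#' and each expanded set is treated as a column of equally probable residues:
#' a singleton keeps its residue (rule `plurality`), a class symbol becomes a
#' tie among the canonical members of its set (resolved by the policy's
#' `tie_break`), and gap characters delete the column (rule `gap_delete`).
#'
#' @param row Gapped consensus row, possibly containing class symbols.
#' @param policy A [consensus_policy()].
#' @param id Identifier for the resulting sequence.
#' @return A `consensus_result`.
#' @export
consensus_from_row <- function(row, policy = consensus_policy(),
                               id = "consensus") {
  row <- normalize_gaps(toupper(row))
  cs <- chars(row)
  sets <- lapply(cs, function(ch) {
    if (ch == GAP_CHAR) GAP_CHAR else expand_symbol(ch, policy$symbol_map)
  })
  decide_set <- function(set, tie_rng) {
    counts <- stats::setNames(rep(1L, length(set)), set)
    if (identical(set, GAP_CHAR))
      return(structure(list(action = "delete", residue = NA_character_,
                            rule = "gap_delete", counts = counts),
                       class = "column_decision"))
    canon <- sort(intersect(set, AA_LETTERS))
    if (!length(canon))
      stop_symbol("symbol set {", paste(set, collapse = ","),
                  "} contains no canonical residue")
    rule <- if (length(canon) == 1L) "plurality" else "tie"
    pick <- if (length(canon) == 1L ||
                policy$tie_break == "alphabetical") 1L
            else tie_rng(length(canon))
    structure(list(action = "residue", residue = canon[pick], rule = rule,
                   counts = counts), class = "column_decision")
  }
  run <- function() {
    tie_rng <- if (policy$tie_break == "seeded-random")
      function(k) sample.int(k, 1L) else NULL
    lapply(sets, decide_set, tie_rng = tie_rng)
  }
  decs <- if (policy$tie_break == "seeded-random")
    with_seed(policy$seed, run()) else run()
  residues <- vapply(decs, function(d)
    if (d$action == "residue") d$residue else "", "")
  if (!any(nzchar(residues)))
    cz_stop("consenzyme_degenerate_error",
            "every column was gap-deleted; the consensus is empty")
  decisions <- data.frame(
    column = seq_along(decs),
    action = vapply(decs, `[[`, "", "action"),
    residue = vapply(decs, function(d)
      if (is.na(d$residue)) "" else d$residue, ""),
    rule = vapply(decs, `[[`, "", "rule"),
    counts = vapply(decs, function(d)
      paste0(names(d$counts), ":", d$counts, collapse = ","), ""),
    stringsAsFactors = FALSE)
  structure(list(consensus = protein_sequence(id,
                                              paste0(residues, collapse = "")),
                 decisions = decisions, policy = policy),
            class = "consensus_result")
}
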