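# Identity-stratified homolog selection: the step that splits a homolog set
# into nested tiers (e.g. >60% and >50% identity to the query enzyme) before
# consensus derivation.

#' Percent identity between two proteins
#'
#' Globally aligns the two sequences and returns the identical fraction under
#' one of two denominator conventions:
#' \describe{
#'   \item{aligned-columns}{matches / columns where neither symbol is a gap
#'     (gap-excluded; the default).}
#'   \item{shorter-sequence}{matches / length of the shorter input.}
#' }
#'
#' @param a,b `protein_seq` objects (or residue strings).
#' @param mode Denominator convention.
#' @param scoring An [align_scoring()] parameter set.
#' @return Identity fraction in `[0, 1]`.
#' @examples
#' pairwise_identity("AAAA", "AAAT")
#' @export
pairwise_identity <- function(a, b,
                              mode = c("aligned-columns", "shorter-sequence"),
                              scoring = align_scoring()) {
  mode <- match.arg(mode)
  a <- as_protein(a, "a"); b <- as_protein(b, "b")
  pair <- global_align(a, b, scoring = scoring)
  ca <- chars(pair$a_gapped); cb <- chars(pair$b_gapped)
  matches <- sum(ca == cb & ca != "-")
  denom <- switch(mode,
    "aligned-columns" = sum(ca != "-" & cb != "-"),
    "shorter-sequence" = min(nchar(a$residues), nchar(b$residues)))
  if (denom == 0L) return(0)
  matches / denom
}

#' Stratify candidate homologs by identity to a query
#'
#' Computes the identity of every candidate to the query and retains those
#' strictly above the threshold (mirroring ">60%" / ">50%" tier definitions).
#'
#' @param query A `protein_seq`.
#' @param candidates List of `protein_seq` (may be empty).
#' @param threshold Identity fraction in (0, 1); candidates with identity
#'   strictly greater are retained.
#' @param mode,scoring Passed to [pairwise_identity()].
#' @return An object of class `identity_report`: a list with `report`
#'   (data.frame of id, identity, retained), `retained` (list of
#'   `protein_seq`), `query_id`, `threshold`.
#' @export
stratify_by_identity <- function(query, candidates, threshold,
                                 mode = c("aligned-columns",
                                          "shorter-sequence"),
                                 scoring = align_scoring()) {
  mode <- match.arg(mode)
  query <- as_protein(query, "query")
  if (!is.numeric(threshold) || threshold <= 0 || threshold >= 1)
    stop_input("'threshold' must be a fraction in (0, 1)")
  if (inherits(candidates, "protein_seq")) candidates <- list(candidates)
  ids <- vapply(seq_along(candidates), function(i) {
    p <- candidates[[i]]
    if (inherits(p, "protein_seq")) p$id else paste0("cand", i)
  }, "")
  identity <- vapply(candidates, function(p)
    pairwise_identity(query, p, mode = mode, scoring = scoring), 0)
  retained_flag <- identity > threshold
  out <- list(
    report = data.frame(id = ids, identity = identity,
                        retained = retained_flag, stringsAsFactors = FALSE),
    retained = lapply(which(retained_flag), function(i)
      as_protein(candidates[[i]], ids[i])),
    query_id = query$id, threshold = threshold)
  class(out) <- "identity_report"
  out
}

#' @export
print.identity_report <- function(x, ...) {
  cat(sprintf(
    "<identity_report> query %s, threshold > %.0f%%: %d of %d retained\n",
    x$query_id, 100 * x$threshold, length(x$retained), nrow(x$report)))
  print.data.frame(x$report, row.names = FALSE, digits = 3)
  invisible(x)
}
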