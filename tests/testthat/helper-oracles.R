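# Independent oracles used by the property tests. These deliberately share no
# code with the package implementation.

AA20 <- c("A", "C", "D", "E", "F", "G", "H", "I", "K", "L",
          "M", "N", "P", "Q", "R", "S", "T", "V", "W", "Y")

# Brute-force per-column consensus oracle: takes the raw character vector of
# one alignment column and applies the rule cascade by direct enumeration.
oracle_column <- function(colchars, tie = "alphabetical",
                          filler = "A", pref = c("N", "Q")) {
  stopifnot(tie == "alphabetical")  # oracle covers the deterministic mode
  tab <- table(colchars)
  top <- max(tab)
  winners <- sort(names(tab)[tab == top])
  residues_only <- setdiff(winners, "-")
  if (identical(winners, "-"))
    return(list(action = "delete", residue = NA_character_))
  if (top == 1 && length(tab) > 1) {
    if ("-" %in% names(tab))
      return(list(action = "residue", residue = filler))
    present <- pref[pref %in% names(tab)]
    return(list(action = "residue",
                residue = if (length(present)) present[1] else pref[1]))
  }
  # unique residue winner, or alphabetical minimum of the tied residues
  list(action = "residue", residue = min(residues_only))
}

oracle_consensus <- function(rows) {
  mat <- do.call(rbind, strsplit(rows, "", fixed = TRUE))
  out <- character(0)
  for (j in seq_len(ncol(mat))) {
    d <- oracle_column(mat[, j])
    if (d$action == "residue") out <- c(out, d$residue)
  }
  paste0(out, collapse = "")
}

# Exhaustive global-alignment score oracle: enumerates every alignment of a
# and b as a path of match/insert/delete moves, scoring gap runs as
# open + len * ext, and returns the maximum total score.
oracle_align_score <- function(a, b, mat, open = 10, ext = 0.5) {
  ac <- strsplit(a, "")[[1]]
  bc <- strsplit(b, "")[[1]]
  rec <- function(i, j, prev) {
    if (i > length(ac) && j > length(bc)) return(0)
    best <- -Inf
    if (i <= length(ac) && j <= length(bc)) {
      s <- mat[ac[i], bc[j]] + rec(i + 1, j + 1, "m")
      best <- max(best, s)
    }
    if (i <= length(ac)) {  # gap in b
      cost <- ext + if (prev == "db") 0 else open
      best <- max(best, rec(i + 1, j, "db") - cost)
    }
    if (j <= length(bc)) {  # gap in a
      cost <- ext + if (prev == "da") 0 else open
      best <- max(best, rec(i, j + 1, "da") - cost)
    }
    best
  }
  rec(1, 1, "m")
}

# Closed-form OLS slope.
oracle_ols_slope <- function(x, y) {
  sum((x - mean(x)) * (y - mean(y))) / sum((x - mean(x))^2)
}

random_protein <- function(len) paste0(sample(AA20, len, replace = TRUE),
                                       collapse = "")

blosum62 <- local({
  env <- new.env()
  utils::data("BLOSUM62", package = "Biostrings", envir = env)
  get("BLOSUM62", envir = env)
})
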