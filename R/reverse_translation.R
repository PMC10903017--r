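# Back-translation of a designed protein into a host-codon-optimized coding
# sequence, with restriction-site (forbidden motif) avoidance on both strands.

#' Read a codon-usage table from TSV
#'
#' Expects tab-separated columns `codon` (DNA triplet), `aa` (one-letter
#' amino acid, `*` for stop) and `rel_freq` (relative frequency of the codon
#' within its amino acid). All 61 sense codons must be present and per-amino-
#' acid frequencies must sum to 1 (tolerance 1e-6).
#'
#' @param path TSV file path.
#' @param organism Label stored with the table.
#' @return An object of class `codon_table`.
#' @export
read_codon_table <- function(path, organism = basename(path)) {
  if (!file.exists(path)) stop_input("file not found: ", path)
  df <- utils::read.delim(path, stringsAsFactors = FALSE)
  codon_table(df, organism = organism)
}

#' Construct a codon-usage table
#'
#' @param df Data frame with columns `codon`, `aa`, `rel_freq`.
#' @param organism Label.
#' @return An object of class `codon_table`.
#' @export
codon_table <- function(df, organism = "unknown") {
  need <- c("codon", "aa", "rel_freq")
  if (!all(need %in% names(df)))
    stop_format("codon table needs columns: ", paste(need, collapse = ", "))
  df$codon <- toupper(df$codon)
  df$aa <- toupper(df$aa)
  df$aa[df$aa == "*"] <- "*"
  if (any(!grepl("^[ACGT]{3}$", df$codon)))
    stop_format("codons must be ACGT triplets")
  if (any(df$rel_freq < 0)) stop_format("frequencies must be non-negative")
  code <- standard_genetic_code()
  sense <- names(code)[code != "*"]
  missing <- setdiff(sense, df$codon)
  if (length(missing))
    stop_format("codon table missing ", length(missing),
                " sense codons (e.g. ", missing[1L], ")")
  wrong <- df$codon[code[df$codon] != ifelse(df$aa == "*", "*", df$aa)]
  if (length(wrong))
    stop_format("codon ", wrong[1L], " assigned to the wrong amino acid")
  sums <- tapply(df$rel_freq, df$aa, sum)
  off <- sums[abs(sums - 1) > 1e-6]
  if (length(off))
    stop_format("per-amino-acid frequencies must sum to 1; '",
                names(off)[1L], "' sums to ", format(off[[1L]]))
  structure(list(table = df[order(df$aa, df$codon), , drop = FALSE],
                 organism = organism),
            class = "codon_table")
}

#' @export
print.codon_table <- function(x, ...) {
  cat(sprintf("<codon_table> %s: %d codons\n", x$organism, nrow(x$table)))
  invisible(x)
}

#' Bundled Pseudomonas putida-style codon-usage table
#'
#' A constructed, GC-rich codon-usage table emulating the strong G/C third-
#' position preference of *Pseudomonas putida* KT2440. The values are
#' synthetic (built by a deterministic rule, not measured from a genome) and
#' are intended as a reasonable default for high-GC hosts; substitute a
#' measured table for any organism via [read_codon_table()].
#'
#' @return A `codon_table`.
#' @export
default_codon_table <- function() {
  path <- system.file("extdata", "pputida_codon_usage_synthetic.tsv",
                      package = "consenzyme", mustWork = TRUE)
  read_codon_table(path, organism = "Pseudomonas putida (synthetic usage)")
}

standard_genetic_code <- function() {
  gc <- Biostrings::GENETIC_CODE
  stats::setNames(as.character(gc), chartr("U", "T", names(gc)))
}

#' Translate a coding sequence with the standard genetic code
#'
#' @param cds DNA string (A/C/G/T), length divisible by 3. A trailing stop
#'   codon is removed; an internal stop raises a premature-stop error naming
#'   the offending codon index.
#' @param id Identifier for the resulting protein.
#' @return A `protein_seq`.
#' @examples
#' translate_cds("ATGTAA")$residues
#' @export
translate_cds <- function(cds, id = "translation") {
  cds <- toupper(cds)
  if (!grepl("^[ACGT]+$", cds)) stop_input("cds must contain only A/C/G/T")
  if (nchar(cds) %% 3L != 0L)
    stop_input("cds length (", nchar(cds), ") is not a multiple of 3")
  n <- nchar(cds) %/% 3L
  starts <- 3L * (seq_len(n) - 1L) + 1L
  codons <- substring(cds, starts, starts + 2L)
  aas <- standard_genetic_code()[codons]
  stops <- which(aas == "*")
  if (length(stops) && stops[1L] < n)
    cz_stop("consenzyme_premature_stop_error",
            "premature stop codon at codon index ", stops[1L])
  if (length(stops)) aas <- aas[-n]
  if (!length(aas)) stop_input("cds encodes no residues")
  protein_sequence(id, paste0(aas, collapse = ""))
}

#' Scan a sequence for motifs on both strands
#'
#' Reports every occurrence of each motif on the forward strand and on the
#' reverse complement (positions always in forward-strand coordinates, 1-based
#' start). A palindromic site is reported once per strand at the same span.
#'
#' @param cds DNA string.
#' @param motifs Character vector of ACGT motifs.
#' @return A `data.frame` with columns `motif`, `strand` (`+`/`-`), `start`.
#' @examples
#' scan_motifs("AAGGATCCTT", "GGATCC")
#' @export
scan_motifs <- function(cds, motifs) {
  cds <- toupper(cds)
  motifs <- toupper(motifs)
  if (length(motifs) && any(!grepl("^[ACGT]+$", motifs)))
    stop_input("motifs must be ACGT strings")
  hits <- list()
  for (m in motifs) {
    fwd <- find_all(cds, m)
    if (length(fwd))
      hits[[length(hits) + 1L]] <- data.frame(motif = m, strand = "+",
                                              start = fwd)
    # an occurrence on the reverse strand = revcomp(motif) on the forward
    rcm <- revcomp(m)
    rev <- find_all(cds, rcm)
    if (length(rev))
      hits[[length(hits) + 1L]] <- data.frame(motif = m, strand = "-",
                                              start = rev)
  }
  if (!length(hits))
    return(data.frame(motif = character(0), strand = character(0),
                      start = integer(0)))
  out <- do.call(rbind, hits)
  out[order(out$start, out$motif, out$strand), , drop = FALSE]
}

find_all <- function(x, pattern) {
  hits <- gregexpr(pattern, x, fixed = TRUE)[[1L]]
  if (hits[1L] == -1L) integer(0) else as.integer(hits)
}

revcomp <- function(x) {
  paste(rev(chars(chartr("ACGT", "TGCA", x))), collapse = "")
}

#' Back-translate a protein into a codon-optimized coding sequence
#'
#' Chooses one codon per residue from a codon-usage table, appends the
#' table's most frequent stop codon, and repairs any occurrence of a
#' forbidden motif (on either strand) by re-choosing, among the codons the
#' motif spans, the synonymous substitution with the smallest frequency cost
#' that removes it. Two modes: `"max-frequency"` (deterministic, the most
#' frequent codon per residue) and `"weighted-sampled"` (codons drawn with
#' probability equal to their relative frequency; reproducible under `seed`).
#'
#' @param protein A `protein_seq` (no X residues).
#' @param table A `codon_table`.
#' @param mode `"max-frequency"` or `"weighted-sampled"`.
#' @param seed Integer seed (required behaviorally for reproducible
#'   weighted sampling).
#' @param forbidden_motifs DNA motifs that must not occur anywhere in the
#'   CDS on either strand; defaults to the BamHI and EcoRI sites, the cloning
#'   sites flanking the synthetic gene.
#' @param flanks Optional named character vector
#'   `c(five = ..., three = ...)` of restriction-site sequences to attach at
#'   the termini of the final construct.
#' @return An object of class `designed_gene` with fields `protein_id`,
#'   `cds`, `construct` (flanked CDS, if flanks given), `flanks`,
#'   `forbidden_motifs`, `mode`, `seed`, `codon_freq_sum`.
#' @examples
#' tab <- default_codon_table()
#' gene <- back_translate(protein_sequence("toy", "MGS"), tab)
#' gene$cds
#' @export
back_translate <- function(protein, table = default_codon_table(),
                           mode = c("max-frequency", "weighted-sampled"),
                           seed = NULL,
                           forbidden_motifs = c("GGATCC", "GAATTC"),
                           flanks = NULL) {
  mode <- match.arg(mode)
  protein <- as_protein(protein)
  if (grepl("X", protein$residues, fixed = TRUE))
    stop_input("protein contains X (unknown) residues; cannot back-translate")
  if (!inherits(table, "codon_table")) stop_input("'table' must be a codon_table")
  forbidden_motifs <- toupper(forbidden_motifs)
  tab <- table$table
  sense <- tab[tab$aa != "*", , drop = FALSE]
  stops <- tab[tab$aa == "*", , drop = FALSE]
  stop_codon <- if (nrow(stops)) stops$codon[which.max(stops$rel_freq)]
                else "TAA"
  by_aa <- split(sense, sense$aa)
  res <- chars(protein$residues)
  choose <- function() {
    codons <- character(length(res))
    if (mode == "max-frequency") {
      best <- vapply(by_aa, function(d) d$codon[which.max(d$rel_freq)], "")
      codons <- unname(best[res])
    } else {
      for (aa in unique(res)) {
        d <- by_aa[[aa]]
        idx <- which(res == aa)
        codons[idx] <- sample(d$codon, length(idx), replace = TRUE,
                              prob = d$rel_freq)
      }
    }
    codons
  }
  codons <- if (mode == "weighted-sampled") with_seed(seed, choose())
            else choose()
  codons <- c(codons, stop_codon)
  codons <- repair_motifs(codons, c(res, "*"), by_aa, stops, forbidden_motifs)
  cds <- paste0(codons, collapse = "")
  freq_lookup <- stats::setNames(tab$rel_freq, paste0(tab$aa, tab$codon))
  construct <- cds
  if (!is.null(flanks)) {
    five <- if ("five" %in% names(flanks)) flanks[["five"]] else ""
    three <- if ("three" %in% names(flanks)) flanks[["three"]] else ""
    construct <- paste0(toupper(five), cds, toupper(three))
  }
  out <- structure(list(
    protein_id = protein$id, cds = cds, construct = construct,
    flanks = flanks, forbidden_motifs = forbidden_motifs, mode = mode,
    seed = seed,
    codon_freq_sum = sum(freq_lookup[paste0(c(res, "*"), codons)])),
    class = "designed_gene")
  # invariants: translation round trip and motif freedom
  stopifnot(identical(translate_cds(cds)$residues, protein$residues),
            nchar(cds) == 3L * (nchar(protein$residues) + 1L))
  if (nrow(scan_motifs(cds, forbidden_motifs)))
    cz_stop("consenzyme_infeasible_error",
            "internal error: motif remained after repair")
  out
}

# Replace codons overlapped by forbidden-motif hits with the synonymous
# alternative of smallest frequency cost that clears the site. Iterates until
# clean; raises a design-infeasible error naming the position when no
# synonymous substitution can remove a hit.
repair_motifs <- function(codons, res, by_aa, stops, motifs, max_iter = 200L) {
  if (!length(motifs)) return(codons)
  for (iter in seq_len(max_iter)) {
    cds <- paste0(codons, collapse = "")
    hits <- scan_motifs(cds, motifs)
    if (!nrow(hits)) return(codons)
    h <- hits[1L, ]
    span <- c(h$start, h$start + nchar(h$motif) - 1L)
    first_codon <- (span[1L] - 1L) %/% 3L + 1L
    last_codon <- (span[2L] - 1L) %/% 3L + 1L
    cand <- list()
    for (ci in first_codon:last_codon) {
      aa <- res[ci]
      alts <- if (aa == "*") stops else by_aa[[aa]]
      if (is.null(alts) || !nrow(alts)) next
      cur_freq <- alts$rel_freq[alts$codon == codons[ci]]
      if (!length(cur_freq)) cur_freq <- 0
      for (k in seq_len(nrow(alts))) {
        if (alts$codon[k] == codons[ci]) next
        cand[[length(cand) + 1L]] <- list(
          ci = ci, codon = alts$codon[k],
          cost = cur_freq - alts$rel_freq[k])
      }
    }
    if (!length(cand))
      cz_stop("consenzyme_infeasible_error",
              "forbidden motif ", h$motif, " at position ", h$start,
              " cannot be removed by a synonymous substitution")
    cand <- cand[order(vapply(cand, `[[`, 0, "cost"))]
    fixed <- FALSE
    for (cc in cand) {
      trial <- codons
      trial[cc$ci] <- cc$codon
      tr_cds <- paste0(trial, collapse = "")
      # accept the cheapest substitution that clears the neighborhood
      win <- substr(tr_cds, max(1L, span[1L] - max(nchar(motifs)) + 1L),
                    min(nchar(tr_cds), span[2L] + max(nchar(motifs)) - 1L))
      if (!nrow(scan_motifs(win, motifs))) {
        codons <- trial
        fixed <- TRUE
        break
      }
    }
    if (!fixed)
      cz_stop("consenzyme_infeasible_error",
              "forbidden motif ", h$motif, " at position ", h$start,
              " cannot be removed by a synonymous substitution")
  }
  cz_stop("consenzyme_infeasible_error",
          "motif repair did not converge")
}

#' @export
print.designed_gene <- function(x, ...) {
  cat(sprintf("<designed_gene> %s: %d nt CDS (%s mode)\n",
              x$protein_id, nchar(x$cds), x$mode))
  if (!is.null(x$flanks))
    cat("  flanked construct:", nchar(x$construct), "nt\n")
  cat("  forbidden motifs:", paste(x$forbidden_motifs, collapse = ", "), "\n")
  invisible(x)
}

#' Write a designed gene as DNA FASTA
#' @param gene A `designed_gene`.
#' @param path Output path.
#' @param what `"cds"` or `"construct"` (flanked).
#' @return `path`, invisibly.
#' @export
write_gene_fasta <- function(gene, path, what = c("cds", "construct")) {
  what <- match.arg(what)
  seqs <- stats::setNames(gene[[what]], gene$protein_id)
  write_fasta(seqs, path)
}
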