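# Protein sequences, families of aligned homologs, and the file formats that
# carry them (aligned FASTA, Clustal, and the MultAlin dialect whose consensus
# rows use class symbols such as '!' for I/V).

#' Construct a protein sequence
#'
#' A lightweight container for a single protein: an identifier, the residue
#' string over the 20 canonical amino-acid letters (X tolerated for unknown
#' residues), and an optional free-text description.
#'
#' @param id Short unique identifier.
#' @param residues Character scalar of amino-acid letters.
#' @param description Optional free text.
#' @return An object of class `protein_seq`.
#' @examples
#' p <- protein_sequence("toy", "MKTAYIAK")
#' nchar(p$residues)
#' @export
protein_sequence <- function(id, residues, description = "") {
  if (!is.character(id) || length(id) != 1L || !nzchar(id))
    stop_input("'id' must be a non-empty character scalar")
  if (!is.character(residues) || length(residues) != 1L || !nzchar(residues))
    stop_input("'residues' must be a non-empty character scalar")
  residues <- toupper(residues)
  bad <- which(!chars(residues) %in% c(AA_LETTERS, "X"))
  if (length(bad))
    stop_alphabet("illegal residue character '",
                  substr(residues, bad[1L], bad[1L]),
                  "' at position ", bad[1L], " in sequence '", id, "'")
  structure(list(id = id, residues = residues,
                 description = as.character(description)),
            class = "protein_seq")
}

#' @export
print.protein_seq <- function(x, ...) {
  cat(sprintf("<protein_seq> %s (%d aa)\n", x$id, nchar(x$residues)))
  res <- x$residues
  if (nchar(res) > 60) res <- paste0(substr(res, 1, 57), "...")
  cat(" ", res, "\n")
  invisible(x)
}

# Coerce a plain character scalar into a protein_seq for convenience.
as_protein <- function(x, id = "seq") {
  if (inherits(x, "protein_seq")) return(x)
  protein_sequence(id, x)
}

#' Remove gap characters from a gapped sequence
#'
#' @param x Character scalar possibly containing `-` gaps.
#' @return The same string with all gaps removed.
#' @export
degap <- function(x) gsub("-", "", x, fixed = TRUE)

normalize_gaps <- function(x) chartr(".~", "--", x)

#' Construct an aligned protein family
#'
#' Holds one multiple sequence alignment: a named set of equal-length gapped
#' sequences. Gap characters `.` and `~` are normalized to `-` on input.
#' Duplicate identifiers are deduplicated by suffixing (with a warning).
#'
#' @param members Named character vector of gapped sequences.
#' @param query_id Optional identifier of the reference member.
#' @param source_format One of `"aligned-fasta"`, `"clustal"`, `"multalin"`.
#' @param consensus_row Optional pre-computed consensus row (gapped string,
#'   possibly containing class symbols) as emitted by MultAlin.
#' @return An object of class `aligned_family`.
#' @examples
#' fam <- aligned_family(c(a = "MK-TA", b = "MKCTA", c = "MKCT-"))
#' alignment_ncol(fam)
#' @export
aligned_family <- function(members, query_id = NULL,
                           source_format = c("aligned-fasta", "clustal",
                                             "multalin"),
                           consensus_row = NULL) {
  source_format <- match.arg(source_format)
  if (!is.character(members) || length(members) < 2L)
    stop_input("an alignment needs at least 2 member sequences")
  if (is.null(names(members)) || any(!nzchar(names(members))))
    names(members) <- paste0("seq", seq_along(members))
  members <- toupper(normalize_gaps(members))
  lens <- nchar(members)
  if (length(unique(lens)) != 1L)
    stop_format("alignment rows have unequal lengths (",
                paste(unique(lens), collapse = ", "), ")")
  # dedupe ids by suffixing
  if (anyDuplicated(names(members))) {
    warning("duplicate sequence identifiers deduplicated by suffixing")
    names(members) <- make.unique(names(members), sep = "_dup")
  }
  for (i in seq_along(members)) {
    res <- degap(members[[i]])
    if (!nzchar(res))
      stop_format("member '", names(members)[i], "' is entirely gaps")
    bad <- which(!chars(res) %in% c(AA_LETTERS, "X"))
    if (length(bad))
      stop_alphabet("illegal character '", chars(res)[bad[1L]],
                    "' in member '", names(members)[i], "'")
  }
  if (!is.null(query_id) && !query_id %in% names(members))
    stop_input("query_id '", query_id, "' is not a member of the alignment")
  structure(list(members = members, query_id = query_id,
                 source_format = source_format,
                 consensus_row = if (is.null(consensus_row)) NULL
                                 else toupper(normalize_gaps(consensus_row))),
            class = "aligned_family")
}

#' Number of alignment columns
#' @param family An `aligned_family`.
#' @return Integer alignment length.
#' @export
alignment_ncol <- function(family) {
  stopifnot(inherits(family, "aligned_family"))
  nchar(family$members[[1L]])
}

#' @export
print.aligned_family <- function(x, ...) {
  cat(sprintf("<aligned_family> %d members x %d columns [%s]\n",
              length(x$members), alignment_ncol(x), x$source_format))
  if (!is.null(x$query_id)) cat("  query:", x$query_id, "\n")
  if (!is.null(x$consensus_row)) cat("  carries a consensus row\n")
  invisible(x)
}

#' Extract one member as an ungapped protein sequence
#' @param family An `aligned_family`.
#' @param id Member identifier.
#' @return A `protein_seq`.
#' @export
family_member <- function(family, id) {
  stopifnot(inherits(family, "aligned_family"))
  if (!id %in% names(family$members))
    stop_input("no member '", id, "' in alignment")
  protein_sequence(id, degap(family$members[[id]]))
}

## ---------------------------------------------------------------- file IO --

read_fasta_raw <- function(path) {
  if (!file.exists(path)) stop_input("file not found: ", path)
  set <- Biostrings::readBStringSet(path)
  seqs <- as.character(set)
  names(seqs) <- vapply(strsplit(names(set), "\\s+"), `[[`, "", 1L)
  seqs
}

#' Read a protein multiple sequence alignment
#'
#' Supports aligned FASTA, Clustal (conservation lines are discarded), and the
#' MultAlin interleaved dialect in which `.` marks gaps and a final
#' `Consensus` row may carry class symbols; that row is kept separately in the
#' returned object, never as a member.
#'
#' @param path File path.
#' @param format `"aligned-fasta"`, `"clustal"`, or `"multalin"`.
#' @param query_id Optional reference member identifier.
#' @return An `aligned_family`.
#' @export
read_alignment <- function(path,
                           format = c("aligned-fasta", "clustal", "multalin"),
                           query_id = NULL) {
  format <- match.arg(format)
  if (!file.exists(path)) stop_input("file not found: ", path)
  if (format == "aligned-fasta") {
    seqs <- read_fasta_raw(path)
    return(aligned_family(seqs, query_id = query_id,
                          source_format = "aligned-fasta"))
  }
  if (format == "clustal") return(read_clustal(path, query_id = query_id))
  read_multalin(path, query_id = query_id)
}

# Clustal interleaved blocks: a CLUSTAL header line, then "<name> <segment>"
# rows with an optional trailing residue count; conservation lines (leading
# whitespace, only *:. symbols) are discarded.
read_clustal <- function(path, query_id = NULL) {
  lines <- readLines(path, warn = FALSE)
  if (!length(lines) || !grepl("^CLUSTAL", lines[1L]))
    stop_format("not a Clustal file (missing CLUSTAL header): ", path)
  lines <- lines[-1L]
  acc <- list()
  order_ids <- character(0)
  for (ln in lines) {
    if (!nzchar(trimws(ln))) next
    if (grepl("^\\s", ln)) next                      # conservation line
    m <- regmatches(ln, regexec(
      "^(\\S+)\\s+([A-Za-z.~-]+)(\\s+\\d+)?\\s*$", ln))[[1L]]
    if (length(m) < 3L)
      stop_format("unparseable Clustal line: '", ln, "'")
    id <- m[2L]
    if (!id %in% order_ids) order_ids <- c(order_ids, id)
    acc[[id]] <- c(acc[[id]], m[3L])
  }
  seqs <- vapply(acc[order_ids], paste0, "", collapse = "")
  aligned_family(seqs, query_id = query_id, source_format = "clustal")
}

# MultAlin interleaved blocks: "<name> <sequence>" lines, blocks separated by
# blank lines; rows named "Consensus" (any case) accumulate the consensus row.
read_multalin <- function(path, query_id = NULL) {
  lines <- readLines(path, warn = FALSE)
  lines <- lines[nzchar(trimws(lines))]
  acc <- list()
  cons <- character(0)
  order_ids <- character(0)
  for (ln in lines) {
    m <- regmatches(ln, regexec("^\\s*(\\S+)\\s+(\\S+)\\s*$", ln))[[1L]]
    if (length(m) != 3L)
      stop_format("unparseable MultAlin line: '", ln, "'")
    id <- m[2L]; seg <- m[3L]
    if (tolower(id) == "consensus") {
      cons <- c(cons, seg)
    } else {
      if (!id %in% order_ids) order_ids <- c(order_ids, id)
      acc[[id]] <- c(acc[[id]], seg)
    }
  }
  seqs <- vapply(acc[order_ids], paste0, "", collapse = "")
  aligned_family(seqs, query_id = query_id, source_format = "multalin",
                 consensus_row = if (length(cons))
                   paste0(cons, collapse = "") else NULL)
}

#' Write an alignment (or plain sequences) as FASTA
#'
#' @param family An `aligned_family`.
#' @param path Output path.
#' @param width Line-wrap width (default 60).
#' @return `path`, invisibly.
#' @export
write_alignment <- function(family, path, width = 60) {
  stopifnot(inherits(family, "aligned_family"))
  write_fasta(family$members, path, width = width)
}

#' Write named sequences to FASTA
#' @param seqs Named character vector, or a list of `protein_seq`.
#' @param path Output path.
#' @param width Line-wrap width.
#' @return `path`, invisibly.
#' @export
write_fasta <- function(seqs, path, width = 60) {
  if (is.list(seqs)) {
    nm <- vapply(seqs, function(p) p$id, "")
    seqs <- vapply(seqs, function(p) p$residues, "")
    names(seqs) <- nm
  }
  con <- file(path, "w")
  on.exit(close(con))
  for (i in seq_along(seqs)) {
    writeLines(paste0(">", names(seqs)[i]), con)
    s <- seqs[[i]]
    starts <- seq(1L, nchar(s), by = width)
    writeLines(substring(s, starts, pmin(starts + width - 1L, nchar(s))), con)
  }
  invisible(path)
}

#' Read unaligned protein FASTA
#' @param path File path.
#' @return A list of `protein_seq`.
#' @export
read_proteins <- function(path) {
  seqs <- read_fasta_raw(path)
  mapply(protein_sequence, names(seqs), unname(seqs),
         SIMPLIFY = FALSE, USE.NAMES = TRUE)
}

## ------------------------------------------------------------- symbol map --

#' Default consensus-class symbol map (MultAlin convention)
#'
#' MultAlin consensus rows mark weakly conserved columns with class symbols
#' rather than residues. The published convention is `!` = I/V, `$` = L/M,
#' `%` = F/Y and `#` = N/D/Q/E (plus the ambiguity codes B/Z). The map is
#' fully overridable: pass any named list of residue sets to [symbol_map()].
#'
#' @return A `symbol_map` object.
#' @export
default_symbol_map <- function() {
  symbol_map(list("!" = c("I", "V"),
                  "$" = c("L", "M"),
                  "%" = c("F", "Y"),
                  "#" = c("N", "D", "Q", "E", "B", "Z")))
}

#' Construct a consensus-class symbol map
#'
#' @param mapping Named list: class symbol -> character vector of residues.
#' @return A `symbol_map` object.
#' @export
symbol_map <- function(mapping) {
  if (!is.list(mapping) || is.null(names(mapping)) ||
      any(!nzchar(names(mapping))))
    stop_input("'mapping' must be a named list of residue sets")
  if (any(names(mapping) %in% AA_LETTERS))
    stop_input("class symbols must be disjoint from the amino-acid alphabet")
  if (any(vapply(mapping, length, 0L) == 0L))
    stop_input("symbol sets must be non-empty")
  mapping <- lapply(mapping, toupper)
  structure(mapping, class = "symbol_map")
}

#' Expand a consensus symbol into the residues it denotes
#'
#' Canonical residues expand to their own singleton set; class symbols expand
#' through the map.
#'
#' @param symbol Single character.
#' @param map A `symbol_map` (default: [default_symbol_map()]).
#' @return Character vector of residues.
#' @examples
#' expand_symbol("A")
#' expand_symbol("!")
#' @export
expand_symbol <- function(symbol, map = default_symbol_map()) {
  if (!is.character(symbol) || length(symbol) != 1L || nchar(symbol) != 1L)
    stop_input("'symbol' must be a single character")
  if (toupper(symbol) %in% AA_LETTERS) return(toupper(symbol))
  if (symbol %in% names(map)) return(map[[symbol]])
  stop_symbol("unknown consensus symbol '", symbol, "'")
}
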