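AA_ALPHABET <- c(strsplit("ACDEFGHIKLMNPQRSTVWY", "")[[1]], "X")

#' Amino-acid sequence record
#'
#' @param id sequence identifier.
#' @param residues amino-acid string over the 20-letter alphabet plus X.
#' @return an object of class `sequence_record`.
#' @export
sequence_record <- function(id, residues) {
  stopifnot(is.character(id), length(id) == 1L,
            is.character(residues), length(residues) == 1L)
  residues <- toupper(gsub("[[:space:]]", "", residues))
  if (nchar(residues) == 0) stop("empty sequence")
  bad <- setdiff(strsplit(residues, "")[[1]], AA_ALPHABET)
  if (length(bad))
    stop("invalid residue letter(s): ", paste(unique(bad), collapse = ", "))
  structure(list(id = id, residues = residues), class = "sequence_record")
}

#' @export
print.sequence_record <- function(x, ...) {
  cat(sprintf("%s: %d aa\n", x$id, nchar(x$residues)))
  invisible(x)
}

#' Read/write FASTA amino-acid files
#'
#' Thin wrappers around Biostrings FASTA I/O returning/consuming
#' [sequence_record()] lists.
#'
#' @param path file path.
#' @return `read_fasta`: list of `sequence_record`s.
#' @export
read_fasta <- function(path) {
  ss <- Biostrings::readAAStringSet(path)
  ids <- sub("\\s.*$", "", names(ss))
  stats::setNames(lapply(seq_along(ss), function(i)
    sequence_record(ids[i], as.character(ss[[i]]))), ids)
}

#' @param records list of [sequence_record()]s (or a single one).
#' @rdname read_fasta
#' @export
write_fasta <- function(records, path) {
  if (inherits(records, "sequence_record")) records <- list(records)
  ss <- Biostrings::AAStringSet(vapply(records, `[[`, character(1), "residues"))
  names(ss) <- vapply(records, `[[`, character(1), "id")
  Biostrings::writeXStringSet(ss, path)
  invisible(path)
}

# Deterministic global alignment used by all sequence operations:
# BLOSUM62, affine gaps (open 10, extend 0.5); "overlap" ignores end gaps.
align_pair <- function(a, b, end_gap_free = FALSE) {
  if (nchar(a$residues) == 0 || nchar(b$residues) == 0) stop("empty sequence")
  aln <- Biostrings::pairwiseAlignment(
    Biostrings::AAString(a$residues), Biostrings::AAString(b$residues),
    substitutionMatrix = "BLOSUM62", gapOpening = 10, gapExtension = 0.5,
    type = if (end_gap_free) "overlap" else "global")
  list(a = as.character(Biostrings::alignedPattern(aln)),
       b = as.character(Biostrings::alignedSubject(aln)),
       score = Biostrings::score(aln))
}

#' Pairwise global sequence identity
#'
#' Aligns two protein sequences globally (BLOSUM62, affine gap penalties: open
#' 10, extend 0.5) and reports percent identity as identical aligned pairs over
#' aligned columns containing at least one residue.
#'
#' @param a,b [sequence_record()] objects.
#' @param end_gap_free use end-gap-free (overlap) alignment instead of strict
#'   global alignment.
#' @return list with `identity` (percent, one decimal), `identity_int`
#'   (rounded integer percent), `matches`, `columns`, and the `alignment`
#'   (aligned strings and score).
#' @examples
#' pairwise_identity(sequence_record("x", "ACDE"),
#'                   sequence_record("y", "ACEE"))$identity
#' @export
pairwise_identity <- function(a, b, end_gap_free = FALSE) {
  stopifnot(inherits(a, "sequence_record"), inherits(b, "sequence_record"))
  aln <- align_pair(a, b, end_gap_free)
  ca <- strsplit(aln$a, "")[[1]]
  cb <- strsplit(aln$b, "")[[1]]
  cols <- ca != "-" | cb != "-"
  matches <- sum(ca == cb & ca != "-")
  pct <- 100 * matches / sum(cols)
  list(identity = round(pct, 1), identity_int = as.integer(round(pct)),
       matches = matches, columns = sum(cols), alignment = aln)
}

# Map a 1-based reference position to the query position through an alignment
# (aligned query string qa, aligned reference string ra). NA when the query has
# a gap at that reference position.
map_position <- function(qa, ra, ref_pos) {
  ca <- strsplit(qa, "")[[1]]
  cr <- strsplit(ra, "")[[1]]
  rpos <- cumsum(cr != "-")
  col <- match(ref_pos, rpos)
  if (is.na(col) || cr[col] == "-") return(NA_integer_)
  if (ca[col] == "-") return(NA_integer_)
  sum(ca[seq_len(col)] != "-")
}

#' Classify a proteorhodopsin's spectral tuning
#'
#' Green- and blue-absorbing proteorhodopsins differ by a single tuning-switch
#' residue (position 106 in BPR numbering; position 94 in E17R): a leucine
#' tunes the pigment green (~525 nm), a glutamine blue (~490 nm). The query is
#' aligned to a BPR-numbered reference and the residue homologous to the switch
#' position is read out.
#'
#' @param q query [sequence_record()].
#' @param ref BPR-numbered reference [sequence_record()].
#' @param ref_position tuning-switch position in the reference (default 106).
#' @param min_identity alignment identity floor in percent (default 30); below
#'   it the query is considered unalignable and an error is thrown.
#' @return list with `class` ("green", "blue" or "unassigned"), `residue` (the
#'   observed switch residue), `query_position` (1-based position in the
#'   query, NA if gapped), and `identity`.
#' @export
classify_spectral_tuning <- function(q, ref, ref_position = 106,
                                     min_identity = 30) {
  stopifnot(inherits(q, "sequence_record"), inherits(ref, "sequence_record"))
  pid <- pairwise_identity(q, ref)
  if (pid$identity < min_identity)
    stop(sprintf("query aligns to the reference at only %.1f%% identity ",
                 pid$identity), "(floor ", min_identity, "%): unalignable")
  qpos <- map_position(pid$alignment$a, pid$alignment$b, ref_position)
  residue <- if (is.na(qpos)) NA_character_ else
    substr(q$residues, qpos, qpos)
  cls <- if (is.na(residue)) "unassigned"
         else if (residue == "L") "green"
         else if (residue == "Q") "blue"
         else "unassigned"
  list(class = cls, residue = residue, query_position = qpos,
       identity = pid$identity)
}

#' Map functional key residues onto a query sequence
#'
#' Transfers annotated positions (proton acceptor, proton donor, the histidine
#' interacting with the acceptor, the Schiff-base lysine, optionally the
#' spectral tuning switch) from a reference onto a query through a global
#' alignment, verifying the expected residue class at each transferred
#' position.
#'
#' @param q query [sequence_record()].
#' @param ref annotated reference [sequence_record()].
#' @param annotations named list/vector of 1-based reference positions; names
#'   among `acceptor`, `donor`, `his_partner`, `schiff_lysine`,
#'   `tuning_switch`.
#' @param min_identity alignment identity floor in percent.
#' @return an object of class `residue_map`: per annotation the query
#'   `position` (NA when unmapped through a gap), the query `residue`, and a
#'   `match` flag telling whether the residue belongs to the expected class
#'   (acceptor D/E, donor K/D/E, his_partner H, schiff_lysine K).
#' @export
map_key_residues <- function(q, ref, annotations, min_identity = 30) {
  stopifnot(inherits(q, "sequence_record"), inherits(ref, "sequence_record"))
  expected <- list(acceptor = c("D", "E"), donor = c("K", "D", "E"),
                   his_partner = "H", schiff_lysine = "K",
                   tuning_switch = c("L", "Q"))
  ann <- as.list(annotations)
  if (is.null(names(ann)) || !all(names(ann) %in% names(expected)))
    stop("annotations must be named among: ",
         paste(names(expected), collapse = ", "))
  pid <- pairwise_identity(q, ref)
  if (pid$identity < min_identity)
    stop("query and reference align below the identity floor")
  out <- lapply(names(ann), function(key) {
    rp <- as.integer(ann[[key]])
    if (rp < 1 || rp > nchar(ref$residues))
      stop("annotated position ", rp, " outside the reference sequence")
    qp <- map_position(pid$alignment$a, pid$alignment$b, rp)
    res <- if (is.na(qp)) NA_character_ else substr(q$residues, qp, qp)
    list(position = qp, residue = res,
         match = !is.na(res) && res %in% expected[[key]])
  })
  names(out) <- names(ann)
  structure(list(map = out, identity = pid$identity,
                 query = q$id, reference = ref$id),
            class = "residue_map")
}

#' @export
print.residue_map <- function(x, ...) {
  cat(sprintf("residue map: %s onto %s (%.1f%% identity)\n",
              x$reference, x$query, x$identity))
  for (key in names(x$map)) {
    m <- x$map[[key]]
    cat(sprintf("  %-13s -> %s%s %s\n", key,
                if (is.na(m$position)) "unmapped" else m$residue,
                if (is.na(m$position)) "" else m$position,
                if (is.na(m$position)) "" else if (m$match) "(expected class)"
                else "(UNEXPECTED residue)"))
  }
  invisible(x)
}

#' Synthetic proteorhodopsin sequence trio
#'
#' Deterministic synthetic stand-ins for the three proteorhodopsins compared in
#' the E17R study, for offline testing of the sequence tools (the real
#' accessions require a database download). The trio reproduces the structural
#' relationships that matter to the analysis, not the real sequences:
#' \itemize{
#'   \item `e17r`: 248 residues (744 coding bp) with the green-tuning leucine
#'     at position 94 and key residues D86 (acceptor), K97 (donor), H58
#'     (acceptor-stabilizing histidine) and K226 (Schiff-base lysine);
#'   \item `esr`: derived by one N-terminal-region deletion, a 7-residue loop
#'     insertion and scattered substitutions, so that its numbering is D85,
#'     K96, H57, K232 and its identity to `e17r` rounds to 85%;
#'   \item `bpr`: a 12-residue N-terminal extension and heavier substitution
#'     load, with the blue-tuning glutamine at position 106 and a glutamate
#'     proton donor (as in blue proteorhodopsins).
#' }
#' The `esr` record carries an `annotations` attribute with its key-residue
#' positions for use with [map_key_residues()].
#'
#' @return named list of [sequence_record()]s: `e17r`, `esr`, `bpr`.
#' @export
synthetic_pr_sequences <- function() {
  aa_freq <- c(A = 9, C = 1, D = 4, E = 4, F = 6, G = 7, H = 2, I = 8, K = 4,
               L = 12, M = 3, N = 3, P = 3, Q = 3, R = 3, S = 6, T = 6, V = 9,
               W = 2, Y = 4)
  base <- with_seed(170L, sample(names(aa_freq), 248, replace = TRUE,
                                 prob = aa_freq))
  key <- c(`58` = "H", `86` = "D", `94` = "L", `97` = "K", `226` = "K")
  base[as.integer(names(key))] <- key
  e17r <- paste(base, collapse = "")

  kp <- as.integer(names(key))
  protected <- sort(unique(c(kp - 1L, kp, kp + 1L)))
  substitute_at <- function(x, n, seed, avoid) {
    cand <- setdiff(seq_along(x), avoid)
    pos <- with_seed(seed, sample(cand, n))
    for (p in pos) {
      alt <- setdiff(names(aa_freq), x[p])
      x[p] <- with_seed(seed + p, sample(alt, 1))
    }
    x
  }
  # ESR: delete residue 30, insert 7 residues after 150, 30 substitutions
  esr <- base
  esr <- substitute_at(esr, 30, seed = 171L,
                       avoid = c(protected, 29:31, 148:153))
  esr <- append(esr[-30], strsplit("GNAQSTP", "")[[1]], after = 149)
  esr_rec <- sequence_record("ESR_synthetic", paste(esr, collapse = ""))
  attr(esr_rec, "annotations") <- list(acceptor = 85L, donor = 96L,
                                       his_partner = 57L, schiff_lysine = 232L,
                                       tuning_switch = 93L)
  # BPR: 12-residue N-terminal extension, 55 substitutions, Q switch, E donor
  bpr <- substitute_at(base, 55, seed = 172L, avoid = protected)
  bpr[94] <- "Q"
  bpr[97] <- "E"
  bpr <- c(strsplit("MGTNLESWLNSA", "")[[1]], bpr)
  bpr_rec <- sequence_record("BPR_synthetic", paste(bpr, collapse = ""))
  attr(bpr_rec, "annotations") <- list(tuning_switch = 106L)

  list(e17r = sequence_record("E17R_synthetic", e17r),
       esr = esr_rec,
       bpr = bpr_rec)
}
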