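ALPHA52 <- c(LETTERS, letters)          # first hybrid character
BASE36 <- c(0:9, LETTERS)               # subsequent digits
CHAIN_IDS <- c(LETTERS, letters, 0:9)   # 62 case-sensitive alphanumerics

#' Fixed-column PDB format limits
#'
#' The constants of the PDB v3.3 fixed-column format that constrain large
#' structures: 62 chain identifiers, 99,999 base-10 atom serials, 9,999
#' base-10 residue numbers, and coordinate fields spanning -999.999 to
#' 9999.999 Angstroms.  The hybrid base-36 numbering extends atoms by
#' 52 x 36^4 = 87,340,032 additional serials and residues by 52 x 36^3 =
#' 2,426,112.
#'
#' @return Named list of limits.
#' @export
pdb_limits <- function() {
  list(max_chain_ids = 62L,
       max_base10_atoms = 99999L,
       max_base10_residues = 9999L,
       coord_min = -999.999,
       coord_max = 9999.999,
       hybrid_atom_capacity = 99999 + 52 * 36^4,
       hybrid_residue_capacity = 9999 + 52 * 36^3)
}

#' Hybrid base-36 atom-serial encoding
#'
#' Serials up to 99,999 are rendered as right-justified decimal.  Above
#' that, the offset `o = index - 100000` is rendered as one case-sensitive
#' alphabetical character (A-Z then a-z, value `o %/% 36^4`) followed by
#' four uppercase base-36 digits (0-9 then A-Z) of `o %% 36^4`.  The
#' alphabetical first character lets any parser recognize the switch from
#' base-10; the scheme is bijective over its full range.
#'
#' @param index positive integer serial(s).
#' @return 5-character field(s).
#' @seealso [decode_atom_serial()]
#' @export
#' @examples
#' encode_atom_serial(c(99999, 100000))
encode_atom_serial <- function(index) {
  vapply(as.numeric(index), function(i) {
    if (is.na(i) || i < 1)
      dx_stop("atom serial must be >= 1", "dx_capacity_error")
    if (i <= 99999) return(formatC(i, width = 5L, format = "d"))
    o <- i - 100000
    if (o >= 52 * 36^4)
      dx_stop(sprintf("atom serial %d exceeds hybrid capacity %d",
                      i, 99999 + 52 * 36^4), "dx_capacity_error")
    paste0(ALPHA52[o %/% 36^4 + 1], encode_base36(o %% 36^4, 4L))
  }, character(1L))
}

#' @rdname encode_atom_serial
#' @param field 5-character encoded field(s).
#' @export
decode_atom_serial <- function(field) {
  vapply(field, function(f) {
    f <- trimws(f)
    first <- substr(f, 1L, 1L)
    if (first %in% ALPHA52) {
      hi <- match(first, ALPHA52) - 1
      lo <- decode_base36(substr(f, 2L, 5L))
      100000 + hi * 36^4 + lo
    } else as.numeric(f)
  }, numeric(1L), USE.NAMES = FALSE)
}

#' Hybrid base-36 residue-number encoding
#'
#' Same scheme as [encode_atom_serial()] with a 4-character field: decimal
#' through 9,999, then one alphabetical character plus three base-36
#' digits, for 52 x 36^3 = 2,426,112 additional residues.
#'
#' @param index positive integer residue number(s).
#' @return 4-character field(s).
#' @export
#' @examples
#' encode_residue_number(c(9999, 10000))
encode_residue_number <- function(index) {
  vapply(as.numeric(index), function(i) {
    if (is.na(i) || i < 1)
      dx_stop("residue number must be >= 1", "dx_capacity_error")
    if (i <= 9999) return(formatC(i, width = 4L, format = "d"))
    o <- i - 10000
    if (o >= 52 * 36^3)
      dx_stop(sprintf("residue number %d exceeds hybrid capacity %d",
                      i, 9999 + 52 * 36^3), "dx_capacity_error")
    paste0(ALPHA52[o %/% 36^3 + 1], encode_base36(o %% 36^3, 3L))
  }, character(1L))
}

#' @rdname encode_residue_number
#' @param field 4-character encoded field(s).
#' @export
decode_residue_number <- function(field) {
  vapply(field, function(f) {
    f <- trimws(f)
    first <- substr(f, 1L, 1L)
    if (first %in% ALPHA52) {
      hi <- match(first, ALPHA52) - 1
      lo <- decode_base36(substr(f, 2L, 4L))
      10000 + hi * 36^3 + lo
    } else as.numeric(f)
  }, numeric(1L), USE.NAMES = FALSE)
}

encode_base36 <- function(o, width) {
  out <- character(width)
  for (k in width:1) {
    out[k] <- BASE36[o %% 36 + 1]
    o <- o %/% 36
  }
  paste(out, collapse = "")
}

decode_base36 <- function(s) {
  digs <- match(strsplit(s, "")[[1L]], BASE36) - 1
  if (anyNA(digs)) dx_stop(sprintf("bad base-36 field '%s'", s),
                           "dx_capacity_error")
  sum(digs * 36^((length(digs) - 1):0))
}

#' Write an atomic structure as a fixed-column PDB file
#'
#' Emits PDB v3.3 ATOM/TER records, one chain per strand.  Chain
#' identifiers cycle through the 62 case-sensitive alphanumerics; when a
#' design has more than 62 strands a sidecar table
#' (`<path>.strandmap.csv`) disambiguates strand-to-chain assignment.
#' Atom serials and per-chain residue numbers switch to the hybrid
#' base-36 encoding beyond the base-10 field capacities.  Coordinates are
#' validated against the fixed-column bounds.
#'
#' @param structure a [build_atoms()] result.
#' @param path output path.
#' @param multimodel emit one MODEL block per strand (some converters
#'   expect multimodel input).
#' @param provenance optional character vector written as REMARK lines.
#' @return `path`, invisibly.
#' @export
write_pdb <- function(structure, path, multimodel = FALSE,
                      provenance = character()) {
  lim <- pdb_limits()
  at <- structure$atoms
  bad <- at$x < lim$coord_min | at$x > lim$coord_max |
    at$y < lim$coord_min | at$y > lim$coord_max |
    at$z < lim$coord_min | at$z > lim$coord_max
  if (any(bad))
    dx_stop(sprintf(
      "%d atom(s) outside the PDB coordinate bounds {-999.999, 9999.999}; recentre the structure",
      sum(bad)), "dx_bounds_error")

  strands <- unique(at$strand)
  n_str <- length(strands)
  chain_of <- CHAIN_IDS[(seq_len(n_str) - 1L) %% 62L + 1L]

  con <- file(path, "w")
  on.exit(close(con))
  if (length(provenance))
    writeLines(sprintf("REMARK 300 %s", provenance), con)
  serial <- 0L
  out <- character(0L)
  flush_out <- function() {
    if (length(out)) writeLines(out, con)
    character(0L)
  }
  for (si in seq_len(n_str)) {
    s <- strands[si]
    rows <- at[at$strand == s, ]
    if (multimodel) out <- c(out, sprintf("MODEL %8d", si))
    ser <- serial + seq_len(nrow(rows))
    name4 <- ifelse(nchar(rows$atom) < 4L,
                    formatC(paste0(" ", rows$atom), width = -4L),
                    rows$atom)
    lines <- paste0(
      "ATOM  ",
      encode_atom_serial(ser),
      " ",
      substr(paste0(name4, "    "), 1L, 4L),
      " ",                                   # altLoc
      formatC(rows$residue, width = 3L),
      " ",
      chain_of[si],
      encode_residue_number(rows$resseq),
      "    ",                                # iCode + gap
      formatC(rows$x, width = 8L, format = "f", digits = 3L),
      formatC(rows$y, width = 8L, format = "f", digits = 3L),
      formatC(rows$z, width = 8L, format = "f", digits = 3L),
      "  1.00  0.00          ",
      formatC(rows$element, width = 2L))
    serial <- serial + nrow(rows)
    last <- rows[nrow(rows), ]
    serial <- serial + 1L
    ter <- paste0("TER   ", encode_atom_serial(serial), "      ",
                  formatC(last$residue, width = 3L), " ", chain_of[si],
                  encode_residue_number(last$resseq))
    out <- c(out, lines, ter)
    if (multimodel) out <- c(out, "ENDMDL")
    if (length(out) > 200000L) out <- flush_out()
  }
  out <- c(out, "END")
  flush_out()

  if (n_str > lim$max_chain_ids) {
    map <- data.frame(strand = strands, chain = chain_of,
                      role = structure$strands$role[match(
                        strands, structure$strands$strand)])
    utils::write.csv(map, paste0(path, ".strandmap.csv"),
                     row.names = FALSE)
  }
  invisible(path)
}

#' Read back a PDB file written by [write_pdb()]
#'
#' Parses ATOM records (including hybrid-encoded serials and residue
#' numbers) into an atom table; used for round-trip validation.
#'
#' @param path PDB file path.
#' @return data.frame with serial, atom, residue, chain, resseq, x, y, z,
#'   element.
#' @export
read_pdb <- function(path) {
  lines <- readLines(path, warn = FALSE)
  rec <- lines[startsWith(lines, "ATOM  ")]
  data.frame(
    serial = decode_atom_serial(substr(rec, 7L, 11L)),
    atom = trimws(substr(rec, 13L, 16L)),
    residue = trimws(substr(rec, 18L, 20L)),
    chain = substr(rec, 22L, 22L),
    resseq = decode_residue_number(substr(rec, 23L, 26L)),
    x = as.numeric(substr(rec, 31L, 38L)),
    y = as.numeric(substr(rec, 39L, 46L)),
    z = as.numeric(substr(rec, 47L, 54L)),
    element = trimws(substr(rec, 77L, 78L)),
    stringsAsFactors = FALSE)
}
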