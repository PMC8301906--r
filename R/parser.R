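#' Slot template for disyllabic items
#'
#' The network's input and output layers are organised as a fixed bank of
#' grapheme/phoneme slots: for each syllable, `onset_slots` consonant
#' slots, one vowel slot, and `coda_slots` consonant slots, in that
#' order.  All items of an experiment share one template.
#'
#' @param n_syllables number of syllables (default 2, matching the
#'   disyllabic stimuli the simulations are built around).
#' @param onset_slots,coda_slots consonant slots per syllable.
#' @return an object of class `slot_template`.
#' @export
slot_template <- function(n_syllables = 2, onset_slots = 3, coda_slots = 2) {
  stopifnot(n_syllables >= 1, onset_slots >= 1, coda_slots >= 0)
  per_syl <- onset_slots + 1L + coda_slots
  roles <- rep(c(rep("onset", onset_slots), "vowel", rep("coda", coda_slots)),
               n_syllables)
  structure(
    list(n_syllables = as.integer(n_syllables),
         onset_slots = as.integer(onset_slots),
         coda_slots = as.integer(coda_slots),
         n_slots = as.integer(n_syllables * per_syl),
         roles = roles,
         syllable = rep(seq_len(n_syllables), each = per_syl)),
    class = "slot_template")
}

#' @exportS3Method base::print
print.slot_template <- function(x, ...) {
  cat(sprintf("<slot_template>: %d syllables x (%d onset + V + %d coda) = %d slots\n",
              x$n_syllables, x$onset_slots, x$coda_slots, x$n_slots))
  invisible(x)
}

#' Segment a spelling into graphemes
#'
#' Greedy longest-match scan from left to right over the table's grapheme
#' inventory; ties cannot arise because graphemes are unique strings.
#' The concatenation of the result always reproduces the input.
#'
#' @param spelling letter string.
#' @param table a [mapping_table()].
#' @return character vector of graphemes.
#' @export
segment <- function(spelling, table) {
  inv <- table$graphemes$grapheme
  inv <- inv[order(nchar(inv), decreasing = TRUE)]
  out <- character(0)
  pos <- 1L
  n <- nchar(spelling)
  while (pos <= n) {
    hit <- NA_character_
    for (g in inv) {
      if (substr(spelling, pos, pos + nchar(g) - 1L) == g) { hit <- g; break }
    }
    if (is.na(hit))
      stop(sprintf("unparseable residue in '%s' at offset %d", spelling, pos))
    out <- c(out, hit)
    pos <- pos + nchar(hit)
  }
  out
}

#' Assign a grapheme sequence to template slots
#'
#' Syllabification is anchored at the vowel graphemes.  Word-initial
#' consonants form the first onset; word-final consonants the last coda.
#' An intervocalic cluster of one consonant resyllabifies entirely as the
#' next onset; larger clusters contribute their first consonant to the
#' preceding coda and the remainder to the following onset (the split
#' Italian-style disyllables such as "tes.ta" exhibit).  Onsets are
#' right-aligned against the vowel slot, codas left-aligned after it.
#'
#' @param graphemes character vector, e.g. from [segment()].
#' @param template a [slot_template()].
#' @param table a [mapping_table()] supplying grapheme classes.
#' @return an object of class `parsed_form`: `slots` (grapheme or `NA`
#'   per slot) plus the source spelling.
#' @export
assign_slots <- function(graphemes, template, table) {
  cls <- grapheme_class(table, graphemes)
  if (anyNA(cls)) stop("grapheme not in table: ",
                       paste(graphemes[is.na(cls)], collapse = ", "))
  v_pos <- which(cls == "vowel")
  n_v <- length(v_pos)
  if (n_v < 1L || n_v > template$n_syllables)
    stop(sprintf("need 1..%d vowel graphemes, found %d",
                 template$n_syllables, n_v))
  per_syl <- template$onset_slots + 1L + template$coda_slots
  slots <- rep(NA_character_, template$n_slots)
  fill <- function(syl, onset, vowel, coda) {
    base <- (syl - 1L) * per_syl
    if (length(onset) > template$onset_slots)
      stop("onset cluster exceeds onset slots")
    if (length(coda) > template$coda_slots)
      stop("coda cluster exceeds coda slots")
    if (length(onset))  # right-aligned against the vowel slot
      slots[base + (template$onset_slots - length(onset) + 1L):template$onset_slots] <<- onset
    slots[base + template$onset_slots + 1L] <<- vowel
    if (length(coda))   # left-aligned after the vowel
      slots[base + template$onset_slots + 1L + seq_along(coda)] <<- coda
  }
  onsets <- vector("list", n_v)
  codas <- vector("list", n_v)
  onsets[[1L]] <- if (v_pos[1L] > 1L) graphemes[1L:(v_pos[1L] - 1L)] else character(0)
  for (i in seq_len(n_v)) codas[[i]] <- character(0)
  if (n_v > 1L) for (i in seq_len(n_v - 1L)) {
    clus <- if (v_pos[i + 1L] - v_pos[i] > 1L)
      graphemes[(v_pos[i] + 1L):(v_pos[i + 1L] - 1L)] else character(0)
    k <- length(clus)
    n_coda <- if (k <= 1L) 0L else 1L
    codas[[i]] <- utils::head(clus, n_coda)
    onsets[[i + 1L]] <- clus[seq_len(k) > n_coda]
  }
  if (v_pos[n_v] < length(graphemes))
    codas[[n_v]] <- graphemes[(v_pos[n_v] + 1L):length(graphemes)]
  for (i in seq_len(n_v))
    fill(i, onsets[[i]], graphemes[v_pos[i]], codas[[i]])
  structure(list(slots = slots, spelling = paste(graphemes, collapse = ""),
                 template = template),
            class = "parsed_form")
}

#' Parse a spelling end to end
#'
#' Convenience composition of [segment()] and [assign_slots()].
#' @inheritParams segment
#' @inheritParams assign_slots
#' @export
parse_spelling <- function(spelling, table, template) {
  assign_slots(segment(spelling, table), template, table)
}

## Unit layout: per slot, one unit per inventory entry plus one "empty"
## unit; unit index of entry k in slot s is (s-1)*(K+1) + k, the empty
## unit is (s-1)*(K+1) + K + 1.
slot_unit <- function(slot, k, inv_size) (slot - 1L) * (inv_size + 1L) + k

active_input_units <- function(parsed, table) {
  inv <- table$graphemes$grapheme
  k <- match(parsed$slots, inv)
  k[is.na(k)] <- length(inv) + 1L
  slot_unit(seq_along(parsed$slots), k, length(inv))
}

active_target_units <- function(parsed, pronunciation, table) {
  inv <- table$phonemes$symbol
  filled <- which(!is.na(parsed$slots))
  if (length(filled) != length(pronunciation))
    stop("pronunciation length does not match filled slots")
  k <- rep(length(inv) + 1L, length(parsed$slots))
  k[filled] <- match(pronunciation, inv)
  if (anyNA(k)) stop("pronunciation contains unknown phonemes")
  slot_unit(seq_along(parsed$slots), k, length(inv))
}

#' Encode a parsed form as an input activation vector
#'
#' One-hot slot coding: per slot, one unit per grapheme of the inventory
#' plus an explicit empty unit; exactly one unit per slot is active, so
#' the L0 norm always equals the number of slots.
#'
#' @param parsed a `parsed_form` from [assign_slots()].
#' @param table the [mapping_table()] whose inventory defines the units.
#' @return binary numeric vector of length
#'   `n_slots * (n_graphemes + 1)`.
#' @export
encode <- function(parsed, table) {
  n_units <- parsed$template$n_slots * (nrow(table$graphemes) + 1L)
  x <- numeric(n_units)
  x[active_input_units(parsed, table)] <- 1
  x
}

#' Decode an input activation vector back to slot contents
#'
#' Inverse of [encode()] for valid one-hot-per-slot vectors.
#' @param x activation vector from [encode()].
#' @param table mapping table defining the unit layout.
#' @param template the [slot_template()].
#' @return character vector of per-slot graphemes (`NA` = empty).
#' @export
decode <- function(x, table, template) {
  inv <- table$graphemes$grapheme
  blk <- length(inv) + 1L
  vapply(seq_len(template$n_slots), function(s) {
    u <- which(x[(s - 1L) * blk + seq_len(blk)] == 1)
    if (length(u) != 1L) stop("not a one-hot-per-slot vector")
    if (u == blk) NA_character_ else inv[u]
  }, character(1))
}
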