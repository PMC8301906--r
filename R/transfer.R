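#' Cross-orthography transfer settings
#'
#' @param tau maximum feature (Hamming) distance at which a
#'   second-language phoneme counts as "featurally close" to a
#'   first-language phoneme and receives its weights (default 0:
#'   counterpart phonemes only, which the synthetic language pairs place
#'   at distance 0).
#' @param scale multiplier in (0, 1] applied to copied weights.
#' @return object of class `transfer_config`.
#' @export
transfer_config <- function(tau = 0, scale = 1) {
  stopifnot(tau >= 0, scale > 0, scale <= 1)
  structure(list(tau = tau, scale = scale), class = "transfer_config")
}

#' Seed a second-language network from a trained first-language network
#'
#' For every grapheme shared by the two orthographies, every
#' first-language phoneme (or empty) output unit with a nonzero weight
#' from that grapheme passes `scale` times its weight to every
#' second-language phoneme within feature distance `tau` of it, in the
#' same slot (weights sum when several source phonemes hit one target).
#' Empty output units transfer to empty output units: the knowledge that
#' a slot is silent is orthography-independent.  All other entries start
#' at zero and the transfer mask is true exactly at the written entries.
#'
#' @param net_l1 trained network of the first language.
#' @param table_l1,table_l2 the two [mapping_table()]s.
#' @param cfg a [transfer_config()].
#' @return an L2-shaped `weight_matrix` with a populated
#'   `transferred_mask`.
#' @export
transfer_weights <- function(net_l1, table_l1, table_l2,
                             cfg = transfer_config()) {
  template <- net_l1$template
  net_l2 <- init_network(template, table_l2)
  net_l2$language_id <- table_l2$language_id

  g1 <- net_l1$graphemes
  g2 <- net_l2$graphemes
  p1 <- net_l1$phonemes
  p2 <- net_l2$phonemes
  shared <- intersect(g1, g2)
  blk_in1 <- length(g1) + 1L
  blk_in2 <- length(g2) + 1L
  blk_out1 <- length(p1) + 1L
  blk_out2 <- length(p2) + 1L

  ## close[[i]] = L2 phoneme indices within tau of L1 phoneme i
  f1 <- table_l1$features[p1, , drop = FALSE]
  f2 <- table_l2$features[p2, , drop = FALSE]
  close <- lapply(seq_along(p1), function(i) {
    d <- colSums(abs(t(f2) - f1[i, ]))
    which(d <= cfg$tau)
  })

  ## input columns: shared graphemes plus the structural empty unit
  col_pairs <- rbind(
    cbind(match(shared, g1), match(shared, g2)),
    cbind(blk_in1, blk_in2))
  for (s in seq_len(template$n_slots)) {
    for (k in seq_len(nrow(col_pairs))) {
      c1 <- (s - 1L) * blk_in1 + col_pairs[k, 1L]
      c2 <- (s - 1L) * blk_in2 + col_pairs[k, 2L]
      w <- net_l1$W[, c1]
      nz <- which(w != 0)
      for (r in nz) {
        s_out <- (r - 1L) %/% blk_out1 + 1L
        u <- r - (s_out - 1L) * blk_out1
        targets <- if (u == blk_out1) blk_out2 else close[[u]]
        for (q in targets) {
          r2 <- (s_out - 1L) * blk_out2 + q
          net_l2$W[r2, c2] <- net_l2$W[r2, c2] + cfg$scale * w[r]
          net_l2$mask[r2, c2] <- TRUE
        }
      }
    }
  }
  net_l2
}

#' Number of transferred weight entries
#'
#' @param net a `weight_matrix`.
#' @return count of true entries of the transfer mask (0 for a
#'   first-language network).
#' @export
count_transferred <- function(net) sum(net$mask)
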