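#' Residue-pair contact persistency
#'
#' A residue pair is in contact in a frame when any heavy-atom
#' (non-hydrogen) pair across the two residues lies within `cutoff`
#' (closed interval: a pair at exactly the cutoff counts). Persistency is
#' the percentage of frames in contact, reported per replica and over the
#' merged frame pool; merging is frame-weighted, so the merged value is
#' the frame-weighted mean of the replica values.
#'
#' Pairs of consecutive residues (|i - j| = 1) are retained but flagged,
#' because network construction must exclude them.
#'
#' @param trajs trajectory or list of replica trajectories.
#' @param sel_a,sel_b selections defining the two residue groups. Equal
#'   groups (intra-molecular scan) require `allow_overlap = TRUE`; then
#'   each unordered residue pair is reported once.
#' @param cutoff distance gate in Angstrom (default 4.5).
#' @param allow_overlap permit overlapping selections (intra mode).
#' @return a `contact_table` data frame: `resno_a`, `resno_b`,
#'   `persistency` (merged, %), `consecutive`, plus one `rep_<k>` column
#'   per replica. Pairs never in contact are included with 0 persistency.
#' @export
contact_persistency <- function(trajs, sel_a, sel_b, cutoff = 4.5,
                                allow_overlap = FALSE) {
  m <- merge_replicas(trajs)
  atom <- m$topology$atom
  ia <- heavy_only(resolve_indices(sel_a), atom)
  ib <- heavy_only(resolve_indices(sel_b), atom)
  if (!length(ia) || !length(ib)) stop("empty selection after removing hydrogens")
  overlap <- length(intersect(atom$resno[ia], atom$resno[ib])) > 0L
  intra <- setequal(atom$resno[ia], atom$resno[ib])
  if (overlap && !allow_overlap)
    stop("selections share residues; set allow_overlap = TRUE for an ",
         "intra-molecular contact scan")
  res_a <- sort(unique(atom$resno[ia]))
  res_b <- sort(unique(atom$resno[ib]))
  Ia <- outer(atom$resno[ia], res_a, `==`) * 1   # atom -> residue indicators
  Ib <- outer(atom$resno[ib], res_b, `==`) * 1
  pairs <- expand.grid(resno_a = res_a, resno_b = res_b,
                       KEEP.OUT.ATTRS = FALSE)
  if (intra) pairs <- pairs[pairs$resno_a < pairs$resno_b, , drop = FALSE]
  else pairs <- pairs[pairs$resno_a != pairs$resno_b | !overlap, , drop = FALSE]
  nrep <- length(m$nframes)
  counts <- matrix(0, nrow(pairs), nrep)
  frame0 <- cumsum(c(0L, m$nframes))
  for (r in seq_len(nrep)) {
    for (f in (frame0[r] + 1L):frame0[r + 1L]) {
      fr <- m$xyz[f, ]
      A <- frame_coords(fr, ia)
      B <- frame_coords(fr, ib)
      d2 <- outer(rowSums(A^2), rowSums(B^2), `+`) - 2 * tcrossprod(A, B)
      hit <- (crossprod(Ia, (d2 <= cutoff^2 + 1e-9) * 1) %*% Ib) > 0
      counts[, r] <- counts[, r] +
        hit[cbind(match(pairs$resno_a, res_a), match(pairs$resno_b, res_b))]
    }
  }
  per_rep <- sweep(counts, 2L, m$nframes, `/`) * 100
  out <- data.frame(pairs,
                    persistency = 100 * rowSums(counts) / sum(m$nframes),
                    consecutive = abs(pairs$resno_a - pairs$resno_b) == 1L)
  for (r in seq_len(nrep)) out[[paste0("rep_", r)]] <- per_rep[, r]
  rownames(out) <- NULL
  class(out) <- c("contact_table", "data.frame")
  attr(out, "nframes") <- m$nframes
  attr(out, "cutoff") <- cutoff
  out
}

heavy_only <- function(idx, atom) idx[atom$elesy[idx] != "H"]

#' Hydrogen-bond persistency
#'
#' A hydrogen bond is present in a frame when the donor--acceptor
#' heavy-atom distance is at most `dist_cutoff` and the donor-H-acceptor
#' angle (at the hydrogen) is at least `angle_cutoff`. With
#' `geometric_only = TRUE` the angle criterion is skipped (for topologies
#' without hydrogens).
#'
#' @param trajs trajectory or list of replica trajectories.
#' @param bonds data frame with atom-index columns `donor`, `hydrogen`,
#'   `acceptor` (`hydrogen` may be `NA` only under `geometric_only`).
#' @param dist_cutoff donor--acceptor distance gate in Angstrom.
#' @param angle_cutoff minimum D-H-A angle in degrees.
#' @param geometric_only skip the angular criterion.
#' @return a `contact_table`-style data frame keyed by donor/acceptor
#'   atoms and their residues, with merged and per-replica persistency.
#' @export
hbond_persistency <- function(trajs, bonds, dist_cutoff = 3.5,
                              angle_cutoff = 120, geometric_only = FALSE) {
  m <- merge_replicas(trajs)
  req <- c("donor", "hydrogen", "acceptor")
  if (!all(req %in% names(bonds)))
    stop("bonds needs columns donor, hydrogen, acceptor")
  if (!geometric_only && anyNA(bonds$hydrogen))
    stop("hydrogen positions are missing; rerun with geometric_only = TRUE ",
         "to apply the distance-only criterion")
  nrep <- length(m$nframes)
  counts <- matrix(0, nrow(bonds), nrep)
  frame0 <- cumsum(c(0L, m$nframes))
  cosmin <- cos(angle_cutoff * pi / 180)
  for (r in seq_len(nrep)) {
    for (f in (frame0[r] + 1L):frame0[r + 1L]) {
      fr <- m$xyz[f, ]
      D <- frame_coords(fr, bonds$donor)
      A <- frame_coords(fr, bonds$acceptor)
      ok <- rowSums((D - A)^2) <= dist_cutoff^2 + 1e-9
      if (!geometric_only) {
        H <- frame_coords(fr, bonds$hydrogen)
        hd <- D - H; ha <- A - H
        cosang <- rowSums(hd * ha) /
          sqrt(rowSums(hd^2) * rowSums(ha^2))
        # angle >= cutoff  <=>  cos(angle) <= cos(cutoff)
        ok <- ok & (cosang <= cosmin + 1e-12)
      }
      counts[, r] <- counts[, r] + ok
    }
  }
  per_rep <- sweep(counts, 2L, m$nframes, `/`) * 100
  atom <- m$topology$atom
  out <- data.frame(donor = bonds$donor, acceptor = bonds$acceptor,
                    resno_a = atom$resno[bonds$donor],
                    resno_b = atom$resno[bonds$acceptor],
                    persistency = 100 * rowSums(counts) / sum(m$nframes))
  out$consecutive <- abs(out$resno_a - out$resno_b) == 1L
  for (r in seq_len(nrep)) out[[paste0("rep_", r)]] <- per_rep[, r]
  class(out) <- c("contact_table", "data.frame")
  attr(out, "nframes") <- m$nframes
  out
}

#' Between-condition contact difference
#'
#' Per-pair change in persistency, `delta = A - B`, over the union of the
#' two tables' residue pairs (a pair absent from one table contributes 0
#' there). When the two conditions have the same replica count the spread
#' is the SD of per-replica differences; otherwise the replica variances
#' are pooled as `sqrt(var_A + var_B)`.
#'
#' @param tab_a,tab_b `contact_table`s sharing a residue universe.
#' @return data frame `resno_a`, `resno_b`, `delta` (percentage points),
#'   `sd`.
#' @export
contact_difference <- function(tab_a, tab_b) {
  stopifnot(inherits(tab_a, "contact_table"), inherits(tab_b, "contact_table"))
  ua <- unique(c(tab_a$resno_a, tab_a$resno_b))
  ub <- unique(c(tab_b$resno_a, tab_b$resno_b))
  if (!length(intersect(ua, ub)))
    stop("contact tables have disjoint residue universes")
  key <- function(d) paste(d$resno_a, d$resno_b, sep = ":")
  keys <- union(key(tab_a), key(tab_b))
  ka <- match(keys, key(tab_a)); kb <- match(keys, key(tab_b))
  reps <- function(tab) grep("^rep_", names(tab), value = TRUE)
  ra <- reps(tab_a); rb <- reps(tab_b)
  pa <- ifelse(is.na(ka), 0, tab_a$persistency[ka])
  pb <- ifelse(is.na(kb), 0, tab_b$persistency[kb])
  get_rep <- function(tab, cols, rows) {
    m <- matrix(0, length(rows), length(cols))
    ok <- !is.na(rows)
    m[ok, ] <- as.matrix(tab[rows[ok], cols, drop = FALSE])
    m
  }
  ma <- get_rep(tab_a, ra, ka); mb <- get_rep(tab_b, rb, kb)
  if (length(ra) == length(rb)) {
    sdv <- apply(ma - mb, 1L, sd)
  } else {
    sdv <- sqrt(apply(ma, 1L, stats::var) + apply(mb, 1L, stats::var))
  }
  rs <- do.call(rbind, strsplit(keys, ":", fixed = TRUE))
  out <- data.frame(resno_a = as.integer(rs[, 1L]),
                    resno_b = as.integer(rs[, 2L]),
                    delta = pa - pb, sd = sdv)
  out[order(out$resno_a, out$resno_b), , drop = FALSE]
}
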