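# Independent brute-force oracles and small fixtures used across tests.
# Oracles deliberately avoid the package's graph/fit machinery.

# --- exhaustive path enumeration on an edge data.frame (from, to, weight) ---

bf_adjacency <- function(edges, n_nodes) {
  adj <- vector("list", n_nodes)
  for (k in seq_len(nrow(edges))) {
    a <- edges$from[k]; b <- edges$to[k]; w <- edges$weight[k]
    adj[[a]] <- rbind(adj[[a]], c(b, w))
    adj[[b]] <- rbind(adj[[b]], c(a, w))
  }
  adj
}

# all simple paths s -> t with their costs (recursive DFS, no pruning)
bf_all_paths <- function(edges, n_nodes, s, t) {
  adj <- bf_adjacency(edges, n_nodes)
  paths <- list(); costs <- numeric()
  walk <- function(v, visited, trail, cost) {
    if (v == t) {
      paths[[length(paths) + 1L]] <<- trail
      costs[length(costs) + 1L] <<- cost
      return()
    }
    nb <- adj[[v]]
    if (is.null(nb)) return()
    for (k in seq_len(nrow(nb))) {
      u <- nb[k, 1L]
      if (!visited[u]) {
        visited[u] <- TRUE
        walk(u, visited, c(trail, u), cost + nb[k, 2L])
        visited[u] <- FALSE
      }
    }
  }
  visited <- rep(FALSE, n_nodes); visited[s] <- TRUE
  walk(s, visited, s, 0)
  list(paths = paths, costs = costs)
}

bf_shortest_cost <- function(edges, n_nodes, s, t) {
  res <- bf_all_paths(edges, n_nodes, s, t)
  if (!length(res$costs)) Inf else min(res$costs)
}

# weighted shortest-path edge betweenness over unordered node pairs,
# counting fractionally across co-optimal paths
bf_edge_betweenness <- function(edges, n_nodes) {
  score <- setNames(rep(0, nrow(edges)),
                    paste(pmin(edges$from, edges$to),
                          pmax(edges$from, edges$to), sep = ":"))
  for (s in seq_len(n_nodes - 1L)) for (t in (s + 1L):n_nodes) {
    res <- bf_all_paths(edges, n_nodes, s, t)
    if (!length(res$costs)) next
    opt <- min(res$costs)
    sel <- which(res$costs <= opt + 1e-9)
    for (i in sel) {
      p <- res$paths[[i]]
      keys <- paste(pmin(p[-length(p)], p[-1L]),
                    pmax(p[-length(p)], p[-1L]), sep = ":")
      score[keys] <- score[keys] + 1 / length(sel)
    }
  }
  score
}

# random connected weighted graph: spanning tree plus extra random edges
random_test_graph <- function(n, extra = n, wmin = 0.2, wmax = 2) {
  from <- integer(); to <- integer()
  for (v in 2:n) { u <- sample.int(v - 1L, 1L); from <- c(from, u); to <- c(to, v) }
  have <- paste(from, to, sep = ":")
  cand <- which(upper.tri(matrix(0, n, n)), arr.ind = TRUE)
  cand_keys <- paste(cand[, 1L], cand[, 2L], sep = ":")
  pool <- setdiff(cand_keys, have)
  if (length(pool) && extra > 0) {
    pick <- sample(pool, min(extra, length(pool)))
    sp <- do.call(rbind, strsplit(pick, ":", fixed = TRUE))
    from <- c(from, as.integer(sp[, 1L])); to <- c(to, as.integer(sp[, 2L]))
  }
  data.frame(from = from, to = to,
             weight = runif(length(from), wmin, wmax))
}

# --- rotation-space brute force for superposition ---

frame_coords <- allodyn:::frame_coords   # atoms x 3 block of an xyz frame

euler_rotation <- function(a, b, c) {
  Rz <- function(t) matrix(c(cos(t), -sin(t), 0, sin(t), cos(t), 0, 0, 0, 1),
                           3L, byrow = TRUE)
  Ry <- function(t) matrix(c(cos(t), 0, sin(t), 0, 1, 0, -sin(t), 0, cos(t)),
                           3L, byrow = TRUE)
  Rz(a) %*% Ry(b) %*% Rz(c)
}

# minimise RMSD over rotations: coarse Euler grid then Nelder-Mead polish
bf_superpose_rmsd <- function(mobile, reference) {
  mc <- sweep(mobile, 2L, colMeans(mobile))
  rc <- sweep(reference, 2L, colMeans(reference))
  obj <- function(ang) {
    R <- euler_rotation(ang[1L], ang[2L], ang[3L])
    sqrt(mean(rowSums((mc %*% t(R) - rc)^2)))
  }
  grid <- seq(0, 2 * pi, length.out = 13L)[-13L]
  bgrid <- seq(0, pi, length.out = 7L)
  best <- NULL
  for (a in grid) for (b in bgrid) for (c in grid) {
    v <- obj(c(a, b, c))
    if (is.null(best) || v < best$v) best <- list(v = v, ang = c(a, b, c))
  }
  opt <- optim(best$ang, obj, method = "Nelder-Mead",
               control = list(maxit = 2000, reltol = 1e-14))
  opt$value
}

# --- fixtures ---

# minimal hand-written PDB text (3 residues, CA + CB each)
three_residue_pdb <- function(path, insert = FALSE) {
  lines <- c(
    "ATOM      1  CA  ALA A   1       0.000   0.000   0.000  1.00  0.00           C",
    "ATOM      2  CB  ALA A   1       1.000   1.000   0.000  1.00  0.00           C",
    "ATOM      3  CA  GLY A   2       3.800   0.000   0.000  1.00  0.00           C",
    "ATOM      4  CB  GLY A   2       4.800   1.000   0.000  1.00  0.00           C",
    sprintf("ATOM      5  CA  SER A   3%s      7.600   0.000   0.000  1.00  0.00           C",
            if (insert) "A" else " "),
    "ATOM      6  CB  SER A   3       8.600   1.000   0.000  1.00  0.00           C",
    "END")
  writeLines(lines, path)
  path
}

# static trajectory placing selected residue pairs at fixed distances:
# coords[i] on the x-axis at the given positions, one CA per residue
static_chain_traj <- function(x_positions, n_frames = 3L) {
  n <- length(x_positions)
  top <- calpha_topology(n)
  xyz <- matrix(rep(as.numeric(t(cbind(x_positions, 0, 0))),
                    each = n_frames), nrow = n_frames)
  trajectory(xyz, top)
}

# contact table built by hand (single replica unless rep columns given)
manual_contact_table <- function(resno_a, resno_b, persistency,
                                 reps = NULL, nframes = 100L) {
  d <- data.frame(resno_a = resno_a, resno_b = resno_b,
                  persistency = persistency,
                  consecutive = abs(resno_a - resno_b) == 1L)
  if (is.null(reps)) d$rep_1 <- persistency
  else for (r in seq_len(ncol(reps))) d[[paste0("rep_", r)]] <- reps[, r]
  class(d) <- c("contact_table", "data.frame")
  attr(d, "nframes") <- rep(nframes, if (is.null(reps)) 1L else ncol(reps))
  d
}

# identity-correlation matrix over given residues
manual_corr <- function(resno, C = NULL) {
  n <- length(resno)
  if (is.null(C)) C <- diag(n)
  dimnames(C) <- list(resno, resno)
  class(C) <- c("corr_matrix", "matrix")
  C
}
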