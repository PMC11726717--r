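#' Select atoms with a small expression grammar
#'
#' Supported terms: `name <atom name>`, `resid <n>` or `resid <a>-<b>`
#' (author residue numbering), `chain <id>`, and `bw <label>` or
#' `bw <h.p1>-<h.p2>` (Ballesteros--Weinstein label or within-helix range,
#' requires a BW map). Terms combine with `and` / `or`; `and` binds
#' tighter. Resolution is deterministic: indices are returned in ascending
#' atom order, so resolving twice, or resolving a reordered expression,
#' gives the same indices.
#'
#' @param topology an `allodyn_topology`.
#' @param expression selection string, e.g. `"name CA"`,
#'   `"resid 240-260 and name CA"`, `"bw 7.40-7.49"`.
#' @return an `allodyn_selection`: list with `expression`, `indices`
#'   (1-based atom indices) and `resno` (residues covered).
#' @export
select_atoms <- function(topology, expression) {
  stopifnot(inherits(topology, "allodyn_topology"), is.character(expression),
            length(expression) == 1L)
  atom <- topology$atom
  expr <- trimws(expression)
  if (!nzchar(expr)) stop("empty selection expression")
  or_parts <- strsplit(expr, "\\s+or\\s+")[[1L]]
  mask <- rep(FALSE, nrow(atom))
  for (part in or_parts) {
    and_terms <- strsplit(trimws(part), "\\s+and\\s+")[[1L]]
    m <- rep(TRUE, nrow(atom))
    for (term in and_terms) m <- m & eval_term(topology, trimws(term))
    mask <- mask | m
  }
  idx <- which(mask)
  if (length(idx) == 0L)
    warning("selection '", expression, "' matched no atoms")
  structure(list(expression = expression, indices = idx,
                 resno = sort(unique(atom$resno[idx]))),
            class = "allodyn_selection")
}

eval_term <- function(topology, term) {
  atom <- topology$atom
  tok <- strsplit(term, "\\s+")[[1L]]
  if (length(tok) != 2L)
    stop("cannot parse selection term '", term,
         "' (expected '<keyword> <value>')")
  key <- tok[1L]; val <- tok[2L]
  switch(key,
    name = atom$elety == val,
    chain = atom$chain == val,
    resid = {
      rng <- parse_int_range(val, term)
      atom$resno >= rng[1L] & atom$resno <= rng[2L]
    },
    bw = {
      if (is.null(topology$bw))
        stop("selection term '", term, "' needs a BW map, none attached")
      keep <- bw_range_residues(topology$bw, val, term)
      atom$resno %in% keep
    },
    stop("unknown selection keyword '", key, "' in term '", term, "'")
  )
}

parse_int_range <- function(val, term) {
  p <- strsplit(val, "-", fixed = TRUE)[[1L]]
  n <- suppressWarnings(as.integer(p))
  if (anyNA(n) || !length(n) %in% 1:2)
    stop("cannot parse residue range in term '", term, "'")
  if (length(n) == 1L) c(n, n) else sort(n)
}

bw_range_residues <- function(bw, val, term) {
  split_bw <- function(s) {
    p <- suppressWarnings(as.integer(strsplit(s, ".", fixed = TRUE)[[1L]]))
    if (length(p) != 2L || anyNA(p)) stop("malformed BW label '", s,
                                          "' in term '", term, "'")
    p
  }
  ends <- strsplit(val, "-", fixed = TRUE)[[1L]]
  if (!length(ends) %in% 1:2) stop("malformed BW term '", term, "'")
  a <- split_bw(ends[1L])
  b <- if (length(ends) == 2L) split_bw(ends[2L]) else a
  if (a[1L] != b[1L]) stop("BW range '", val, "' must stay within one helix")
  lab <- do.call(rbind, lapply(bw$bw, split_bw))
  hit <- lab[, 1L] == a[1L] & lab[, 2L] >= min(a[2L], b[2L]) &
    lab[, 2L] <= max(a[2L], b[2L])
  if (!any(hit) && length(ends) == 1L)
    stop("BW label '", val, "' has no mapping")
  bw$resno[hit]
}

#' @export
print.allodyn_selection <- function(x, ...) {
  cat("<allodyn_selection> '", x$expression, "': ", length(x$indices),
      " atoms, ", length(x$resno), " residues\n", sep = "")
  invisible(x)
}
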