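#' Read a PDB topology
#'
#' Parses a PDB file into the pipeline's topology representation: an atom
#' table keyed by the author residue numbering of the file, optionally
#' overlaid with a Ballesteros--Weinstein (BW) map. Author numbering is the
#' canonical residue key throughout the package; BW labels are an overlay
#' used for selection and reporting, never a primary key.
#'
#' Only the plain PDB dialect is supported: records carrying insertion
#' codes or alternate locations are rejected rather than silently
#' reinterpreted, because either would make the residue key ambiguous.
#'
#' @param path path to a PDB file.
#' @param bw_map optional BW overlay: either a CSV path with columns
#'   `resno,bw` (e.g. `279,7.44`) or a data frame with those columns.
#' @return an object of class `allodyn_topology`: a list with `atom`
#'   (data frame: `eleno`, `elety`, `resno`, `resid`, `chain`, `elesy`),
#'   `bw` (the overlay or `NULL`) and `natom`.
#' @export
read_topology <- function(path, bw_map = NULL) {
  if (!file.exists(path)) stop("topology file not found: ", path)
  pdb <- tryCatch(bio3d::read.pdb(path, verbose = FALSE),
                  error = function(e) stop("failed to parse PDB '", path, "': ",
                                           conditionMessage(e)))
  atom <- pdb$atom
  ins <- atom$insert
  if (any(!is.na(ins) & nzchar(trimws(ins))))
    stop("PDB '", path, "' uses insertion codes; this dialect is unsupported ",
         "(residue keys would be ambiguous)")
  alt <- atom$alt
  if (any(!is.na(alt) & nzchar(trimws(alt))))
    stop("PDB '", path, "' uses alternate locations; this dialect is unsupported")
  elesy <- atom$elesy
  if (is.null(elesy) || all(is.na(elesy)) || all(!nzchar(trimws(elesy))))
    elesy <- guess_element(atom$elety)
  elesy <- toupper(trimws(elesy))
  miss <- is.na(elesy) | !nzchar(elesy)
  elesy[miss] <- guess_element(atom$elety[miss])
  top <- structure(
    list(atom = data.frame(eleno  = seq_len(nrow(atom)),
                           elety  = trimws(atom$elety),
                           resno  = atom$resno,
                           resid  = trimws(atom$resid),
                           chain  = ifelse(is.na(atom$chain), "A", atom$chain),
                           elesy  = elesy,
                           stringsAsFactors = FALSE),
         bw = NULL, natom = nrow(atom), xyz = as.numeric(pdb$xyz)),
    class = "allodyn_topology")
  if (!is.null(bw_map)) top <- attach_bw_map(top, bw_map)
  top
}

guess_element <- function(elety) {
  nm <- gsub("[0-9']", "", trimws(elety))
  two <- toupper(substr(nm, 1, 2))
  one <- toupper(substr(nm, 1, 1))
  ifelse(two %in% c("CL", "BR", "NA", "MG", "ZN", "FE", "SE"), two, one)
}

#' Attach a Ballesteros--Weinstein map to a topology
#'
#' @param topology an `allodyn_topology`.
#' @param bw_map CSV path or data frame with columns `resno`, `bw`.
#' @return the topology with the `bw` overlay attached.
#' @export
attach_bw_map <- function(topology, bw_map) {
  stopifnot(inherits(topology, "allodyn_topology"))
  if (is.character(bw_map)) {
    bw_map <- read.csv(bw_map, stringsAsFactors = FALSE,
                       colClasses = c("integer", "character"))
  }
  if (!all(c("resno", "bw") %in% names(bw_map)))
    stop("BW map must have columns 'resno' and 'bw'")
  bw_map$resno <- as.integer(bw_map$resno)
  bw_map$bw <- trimws(as.character(bw_map$bw))
  if (anyDuplicated(bw_map$bw))
    stop("BW map assigns a label to more than one residue: ",
         paste(bw_map$bw[duplicated(bw_map$bw)], collapse = ", "))
  known <- unique(topology$atom$resno)
  bad <- setdiff(bw_map$resno, known)
  if (length(bad))
    stop("BW map references residues absent from the topology: ",
         paste(bad, collapse = ", "))
  topology$bw <- bw_map[c("resno", "bw")]
  topology
}

#' Resolve a Ballesteros--Weinstein label to a residue number
#'
#' @param topology an `allodyn_topology` with a BW overlay.
#' @param label a BW label such as `"7.44"`.
#' @return the author residue number.
#' @export
bw_residue <- function(topology, label) {
  stopifnot(inherits(topology, "allodyn_topology"))
  if (is.null(topology$bw)) stop("topology has no BW map attached")
  hit <- topology$bw$resno[topology$bw$bw == label]
  if (length(hit) != 1L) stop("BW label '", label, "' has no unique mapping")
  hit
}

#' @export
print.allodyn_topology <- function(x, ...) {
  cat("<allodyn_topology> ", x$natom, " atoms, ",
      length(unique(x$atom$resno)), " residues",
      if (!is.null(x$bw)) paste0(", BW map (", nrow(x$bw), " labels)"), "\n",
      sep = "")
  invisible(x)
}

#' Write a topology (with coordinates) as PDB
#'
#' @param topology an `allodyn_topology`.
#' @param xyz coordinates to write, length `3 * natom` (defaults to the
#'   coordinates read/generated with the topology).
#' @param path output file.
#' @return `path`, invisibly.
#' @export
write_topology_pdb <- function(topology, path, xyz = topology$xyz) {
  stopifnot(inherits(topology, "allodyn_topology"))
  if (length(xyz) != 3L * topology$natom)
    stop("coordinate length does not match topology atom count")
  a <- topology$atom
  bio3d::write.pdb(file = path, xyz = as.numeric(xyz), resno = a$resno,
                   resid = a$resid, eleno = a$eleno, elety = a$elety,
                   chain = a$chain, elesy = a$elesy)
  invisible(path)
}
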