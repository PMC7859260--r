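#' Load a CG trajectory from GRO topology plus GRO or TRR trajectory
#'
#' Reads backbone (BB) bead coordinates of a coarse-grained helix bundle.
#' The topology GRO file defines atom names and residue numbers; the
#' trajectory file supplies per-frame coordinates and box. A text
#' multi-frame GRO file or a binary single-precision TRR file can serve as
#' the trajectory; when `trajectory` is `NULL` the topology's own
#' configuration(s) are used.
#'
#' @param topology path to the GRO topology/configuration file.
#' @param trajectory optional path to a multi-frame GRO or TRR file.
#' @param bb_selection atom-name selection for backbone beads (default
#'   `"BB"`, the Martini backbone bead name).
#' @param helix_grouping how to partition the selected beads into helices:
#'   either a single integer (residues per helix; beads are split into
#'   consecutive equal runs) or a list of `c(start, end)` residue-number
#'   ranges, one per helix, in topology numbering.
#' @param covalent_pairs optional list of helix-index pairs that are
#'   covalently linked (e.g. disulphide-bonded dimers); stored as metadata
#'   only, the helices stay separate.
#' @param variant optional peptide variant label.
#' @return a `bundle_trajectory`; frame times in ns.
#' @export
load_cg_trajectory <- function(topology, trajectory = NULL, bb_selection = "BB",
                               helix_grouping, covalent_pairs = NULL,
                               variant = NA_character_) {
  top <- read_gro(topology)[[1]]
  sel <- which(top$atoms$atom == bb_selection)
  if (!length(sel))
    stop("selection '", bb_selection, "' matches no beads in ", topology)
  resno <- top$atoms$resno[sel]

  groups <- if (is.numeric(helix_grouping) && length(helix_grouping) == 1L) {
    if (length(sel) %% helix_grouping != 0L)
      stop(length(sel), " selected beads cannot be split into helices of ",
           helix_grouping, " residues")
    split(seq_along(sel), ceiling(seq_along(sel) / helix_grouping))
  } else {
    lapply(helix_grouping, function(rg) {
      idx <- which(resno >= rg[[1]] & resno <= rg[[2]])
      if (!length(idx))
        stop("residue range ", rg[[1]], "-", rg[[2]], " selects no beads")
      idx
    })
  }
  nper <- lengths(groups)
  if (length(unique(nper)) != 1L)
    stop("unequal helix lengths for one variant: ",
         paste(unique(nper), collapse = ", "), " residues")

  make_frame <- function(xyz_all, box, time) {
    helices <- lapply(groups, function(idx)
      helix_beads(xyz_all[idx, , drop = FALSE], resno = resno[idx],
                  resname = top$atoms$resname[sel][idx]))
    bundle_frame(helices, time = time, box = box, periodic = TRUE)
  }

  frames <- if (is.null(trajectory)) {
    lapply(read_gro(topology), function(fr)
      make_frame(as.matrix(fr$atoms[sel, c("x", "y", "z")]), fr$box, fr$time))
  } else if (grepl("\\.trr$", trajectory, ignore.case = TRUE)) {
    trr <- read_trr(trajectory)
    lapply(trr, function(fr) {
      if (fr$natoms != nrow(top$atoms))
        stop("topology has ", nrow(top$atoms), " atoms but trajectory frame has ",
             fr$natoms)
      make_frame(fr$xyz[sel, , drop = FALSE], fr$box, fr$time / 1000)  # ps -> ns
    })
  } else {
    lapply(read_gro(trajectory), function(fr) {
      if (fr$natoms != nrow(top$atoms))
        stop("topology has ", nrow(top$atoms), " atoms but trajectory frame has ",
             fr$natoms)
      make_frame(as.matrix(fr$atoms[sel, c("x", "y", "z")]), fr$box, fr$time)
    })
  }

  traj <- bundle_trajectory(frames, variant = variant,
                            source = c(topology, trajectory))
  if (!is.null(covalent_pairs)) traj$covalent_pairs <- covalent_pairs
  traj
}
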