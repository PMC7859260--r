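#' Load a multi-model PDB ensemble as a bundle trajectory
#'
#' Reads an NMR-style multi-model PDB file (e.g. the 2mic, 2na7 or 6nhw
#' ensembles) and treats each model as one trajectory snapshot. The CG
#' backbone (BB) bead of each residue is taken from its CA atom; the
#' Martini BB bead sits at the backbone centre of mass, within about
#' 0.07 nm of the CA, an accepted approximation at the bead scale
#' analysed here. Frame time is the model ordinal (0, 1, ...).
#'
#' PDB files carry no periodic box; frames get `box_default` and are
#' flagged non-periodic so distance code never applies minimum-image
#' wrapping to them. A CRYST1 record with non-trivial cell overrides the
#' default (still non-periodic).
#'
#' @param path path to the PDB file.
#' @param helix_assignment character vector of chain identifiers, in helix
#'   order; each listed chain becomes one helix. `NULL` uses every chain
#'   present, in order of appearance.
#' @param box_default box used for the non-periodic frames, nm.
#' @param variant optional peptide variant label for the metadata.
#' @return a `bundle_trajectory` with one frame per model.
#' @export
load_multimodel_structure <- function(path, helix_assignment = NULL,
                                      box_default = c(25, 25, 10),
                                      variant = NA_character_) {
  pdb <- bio3d::read.pdb(path, multi = TRUE, verbose = FALSE)
  atom <- pdb$atom
  ca <- which(atom$elety == "CA" & atom$type %in% c("ATOM", "HETATM"))
  if (!length(ca)) stop("no CA atoms found in ", path)
  chains <- atom$chain[ca]
  chains[is.na(chains)] <- " "
  if (is.null(helix_assignment)) helix_assignment <- unique(chains)
  xyz <- pdb$xyz
  if (is.null(dim(xyz))) xyz <- matrix(xyz, nrow = 1)
  n_models <- nrow(xyz)

  box <- box_default
  if (!is.null(pdb$cryst1) && length(pdb$cryst1$abc) == 3 &&
      all(is.finite(pdb$cryst1$abc)) && any(pdb$cryst1$abc > 2))
    box <- pdb$cryst1$abc / 10

  frames <- vector("list", n_models)
  for (m in seq_len(n_models)) {
    helices <- vector("list", length(helix_assignment))
    for (h in seq_along(helix_assignment)) {
      ch <- helix_assignment[[h]]
      sel <- ca[chains == ch]
      if (!length(sel))
        stop("chain '", ch, "' not present in model ", m, " of ", path)
      resno <- atom$resno[sel]
      miss <- setdiff(seq(min(resno), max(resno)), resno)
      if (length(miss))
        stop("chain '", ch, "' has residue gaps: missing ",
             paste(miss, collapse = ", "))
      coords <- cbind(xyz[m, 3 * sel - 2], xyz[m, 3 * sel - 1], xyz[m, 3 * sel]) / 10
      helices[[h]] <- helix_beads(coords, resno = resno,
                                  resname = atom$resid[sel])
    }
    frames[[m]] <- bundle_frame(helices, time = m - 1, box = box,
                                periodic = FALSE)
  }
  bundle_trajectory(frames, variant = variant, source = path)
}

#' Write a bundle trajectory as a multi-model PDB file
#'
#' Each frame becomes one MODEL; each helix one chain (A, B, C, ...); each
#' BB bead one CA pseudo-atom. Coordinates are converted nm to Angstrom at
#' the format's 0.001 A precision, so round-trips preserve positions to
#' well under 0.001 nm.
#'
#' @param traj a `bundle_trajectory`.
#' @param path output path.
#' @return `path`, invisibly.
#' @export
write_multimodel_pdb <- function(traj, path) {
  con <- file(path, "w")
  on.exit(close(con))
  b <- traj$frames[[1]]$box * 10
  writeLines(sprintf("CRYST1%9.3f%9.3f%9.3f%7.2f%7.2f%7.2f P 1           1",
                     b[1], b[2], b[3], 90, 90, 90), con)
  chain_ids <- c(LETTERS, letters, 0:9)
  for (m in seq_along(traj$frames)) {
    fr <- traj$frames[[m]]
    writeLines(sprintf("MODEL     %4d", m), con)
    serial <- 0L
    for (h in seq_along(fr$helices)) {
      hx <- fr$helices[[h]]
      for (k in seq_len(nrow(hx$xyz))) {
        serial <- serial + 1L
        writeLines(sprintf(
          "ATOM  %5d  CA  %-3s %s%4d    %8.3f%8.3f%8.3f%6.2f%6.2f           C",
          serial, substr(hx$resname[k], 1, 3),
          chain_ids[(h - 1L) %% length(chain_ids) + 1L], hx$resno[k],
          hx$xyz[k, 1] * 10, hx$xyz[k, 2] * 10, hx$xyz[k, 3] * 10, 1, 0), con)
      }
      writeLines("TER", con)
    }
    writeLines("ENDMDL", con)
  }
  writeLines("END", con)
  invisible(path)
}
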