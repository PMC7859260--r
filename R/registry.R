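#' @title Transmembrane peptide registry
#' @description
#' Registry of the TNFR-superfamily transmembrane peptides handled by the
#' package: the p75 (TNFR16), Fas (TNFR6/CD95) and DR5 (TNFRSF10B)
#' transmembrane segments, in the simulated variants plus the NMR reference
#' constructs (PDB 2mic, 2mjo, 2na7, 6nhw). Sequences are 1-letter codes
#' with author residue numbering of the first residue.
#' @keywords internal
.peptides <- local({
  rec <- function(name, start, seq, notes = "") {
    list(name = name, sequence = seq, start_number = as.integer(start),
         end_number = as.integer(start + nchar(seq) - 1L), notes = notes)
  }
  lst <- list(
    rec("p75 NMR (2mic)",  244, "MTRGTTDNLIPVYCSILAAVVVGLVAYIAFKRWNSSKQNKQ",
        "NMR reference, disulphide-linked dimer"),
    rec("p75 dimer (SS)",  248, "TTDNLIPVYCSILAAVVVGLVAYIAFKRWNSS",
        "disulphide-bonded dimer (oxidised C257)"),
    rec("p75 (SH)",        248, "TTDNLIPVYCSILAAVVVGLVAYIAFKRWNSS",
        "reduced monomer, free C257"),
    rec("p75 NMR (2mjo)",  244, "MTRGTTDNLIPVYASILAAVVVGLVAYIAFKRWNSSKQNKQ",
        "NMR reference of the C257A mutant"),
    rec("p75 (C257A)",     248, "TTDNLIPVYASILAAVVVGLVAYIAFKRWNSS",
        "C257A point mutant"),
    rec("Fas NMR (2na7)",  171, "RSNLGWLSLLLLPIPLIVWVKRKEVQKT",
        "NMR reference (C178S construct)"),
    rec("Fas wt",          171, "RSNLGWLCLLLLPIPLIVWVKRKE", "wild type"),
    rec("Fas C178S",       171, "RSNLGWLSLLLLPIPLIVWVKRKE", "C178S (NMR construct)"),
    rec("Fas C178R",       171, "RSNLGWLRLLLLPIPLIVWVKRKE", "C178R"),
    rec("DR5 NMR (6nhw)",  207, "MPGSLSGIIIGVTVAAVVLIVAVFVCKSLLWKKVL",
        "NMR reference (C209G construct)"),
    rec("DR5 wt",          207, "SPCSLSGIIIGVTVAAVVLIVAVFVCKSLLWKKVL", "wild type"),
    rec("DR5 A222Y",       207, "SPCSLSGIIIGVTVAYVVLIVAVFVCKSLLWKKVL", "A222Y"),
    rec("DR5 G217Y",       207, "SPCSLSGIIIYVTVAAVVLIVAVFVCKSLLWKKVL", "G217Y")
  )
  names(lst) <- vapply(lst, `[[`, character(1), "name")
  lst
})

# forgiving name matching: case, spaces, dashes and parentheses ignored
.canon_name <- function(x) gsub("[^a-z0-9]", "", tolower(x))

#' Look up a transmembrane peptide variant
#'
#' Returns the registry record for one of the simulated peptide variants or
#' NMR reference constructs. Matching ignores case, punctuation and spacing,
#' so `"Fas wt"`, `"fas-wt"` and `"Fas WT"` are equivalent.
#'
#' @param name variant label, e.g. `"Fas wt"`, `"DR5 wt"`, `"p75 dimer (SS)"`.
#' @return a `peptide_record` list: `name`, `sequence` (1-letter string),
#'   `start_number`, `end_number`, `notes`.
#' @examples
#' peptide_registry("Fas wt")$sequence
#' peptide_names()
#' @export
peptide_registry <- function(name) {
  key <- .canon_name(name)
  hit <- which(vapply(names(.peptides), .canon_name, character(1)) == key)
  if (!length(hit))
    stop("unknown peptide variant '", name, "'; valid names are: ",
         paste(names(.peptides), collapse = ", "))
  structure(.peptides[[hit[[1]]]], class = "peptide_record")
}

#' List all registered peptide variant names
#' @return character vector of valid `peptide_registry()` names.
#' @export
peptide_names <- function() names(.peptides)

#' @export
print.peptide_record <- function(x, ...) {
  cat(x$name, ": ", x$start_number, "-", x$sequence, "-", x$end_number,
      " (", nchar(x$sequence), " residues)\n", sep = "")
  if (nzchar(x$notes)) cat("  ", x$notes, "\n", sep = "")
  invisible(x)
}

#' Per-residue labels for a registered variant
#' @param name variant label.
#' @return data.frame with `resno` (author number) and `aa` (1-letter code).
#' @export
peptide_residues <- function(name) {
  p <- peptide_registry(name)
  data.frame(resno = p$start_number:p$end_number,
             aa = strsplit(p$sequence, "")[[1]],
             stringsAsFactors = FALSE)
}
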