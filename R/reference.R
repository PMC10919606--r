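#' Synthetic dsrB assay panel
#'
#' Three qPCR primer sets targeting the dissimilatory sulfite reductase
#' beta-subunit (dsrB) gene, with increasing degeneracy:
#' DSRp2060F/DSR4R (forward/reverse degeneracy 4/1, the target-specific
#' assay), DSR1728Fmix/DSR4Rmix (77/10), and DSR1762Fmix/DSR2107Rmix
#' (98/29). The oligo sequences are synthetic stand-ins: they are not the
#' published oligos but are constructed to carry the published degeneracy
#' of each mix and the published binding structure on the companion
#' [dsrb_gblocks()] panel, so the panel reproduces the assay-coverage
#' geometry of the real primer sets.
#'
#' @return Named list of three [primer_set()] objects.
#' @seealso [dsrb_gblocks()], [dsrb_reference()]
#' @export
dsrb_primer_sets <- function() {
  fwd <- function(name, seq) degenerate_primer(name, seq, "forward")
  rev <- function(name, seq) degenerate_primer(name, seq, "reverse")
  list(
    `DSRp2060F/DSR4R` = primer_set(
      "DSRp2060F/DSR4R",
      forward_mix = list(fwd("DSRp2060F", "CAACATCGTYCAYACCCAGG")),      # 4
      reverse_mix = list(rev("DSR4R", "GTGTAGCAGTTACCGCA"))              # 1
    ),
    `DSR1728Fmix/DSR4Rmix` = primer_set(
      "DSR1728Fmix/DSR4Rmix",
      forward_mix = list(                                                # 64+12+1 = 77
        fwd("DSR1728F-a", "ACARGGNTAYGGNTTCGA"),
        fwd("DSR1728F-b", "CCARGGHTAYGGCTTCGA"),
        fwd("DSR1728F-c", "GCAAGGCTATGGCTTCGA")
      ),
      reverse_mix = list(                                                # 8+2 = 10
        rev("DSR4Rmix-a", "ATGTAGCNGTTACCRCA"),
        rev("DSR4Rmix-b", "CTGTAGCAGTTACCRCA")
      )
    ),
    `DSR1762Fmix/DSR2107Rmix` = primer_set(
      "DSR1762Fmix/DSR2107Rmix",
      forward_mix = list(                                                # 64+32+2 = 98
        fwd("DSR1762F-a", "ATGGNCAYACNATGRGCA"),
        fwd("DSR1762F-b", "CTGGNCAYACNATGGGCA"),
        fwd("DSR1762F-c", "GTGGACAYACAATGGGCA")
      ),
      reverse_mix = list(                                                # 16+12+1 = 29
        rev("DSR2107R-a", "AGGRTTNCCYTGACCGTA"),
        rev("DSR2107R-b", "CGGRTTHCCYTGACCGTA"),
        rev("DSR2107R-c", "GGGATTACCTTGACCGTA")
      )
    )
  )
}

# Concrete binding-site implants (one member oligo of each mix, ambiguities
# resolved). Reverse-primer sites are implanted as the reverse complement.
.dsrb_implants <- function() {
  list(
    A_f = "CAACATCGTCCACACCCAGG",            # DSRp2060F, Y -> C, Y -> C
    A_r = reverse_complement("GTGTAGCAGTTACCGCA"),
    B_f = "GCAAGGCTATGGCTTCGA",              # DSR1728F-c (degeneracy-1 member)
    B_r = reverse_complement("CTGTAGCAGTTACCGCA"),  # DSR4Rmix-b, R -> G
    C_f = "GTGGACACACAATGGGCA",              # DSR1762F-c, Y -> C
    C_r = reverse_complement("GGGATTACCTTGACCGTA")  # DSR2107R-c
  )
}

# Panel geometry: which assays each gBlock binds, where sites are implanted,
# and which sites carry a single deliberate mismatch. Membership counts are
# 7 / 8 / 9 for the specific, mid- and high-degeneracy assays, with four
# gBlocks bound by all three ("common"), four by exactly two, four by one.
.dsrb_panel <- function() {
  members <- list(
    gBlock1  = c("A", "C"),
    gBlock2  = "C",
    gBlock3  = "C",
    gBlock4  = c("A", "B", "C"),
    gBlock5  = c("A", "B", "C"),
    gBlock6  = "B",
    gBlock7  = "B",
    gBlock8  = c("A", "B", "C"),
    gBlock9  = c("A", "B"),
    gBlock10 = c("A", "C"),
    gBlock11 = c("A", "B", "C"),
    gBlock12 = c("B", "C")
  )
  # (gBlock, site) implants carrying one mismatch instead of a perfect match
  one_mm <- list(gBlock3 = "C_f", gBlock7 = "B_f")
  supercluster <- c(
    gBlock1 = "Deltaproteobacteria", gBlock2 = "Environmental cluster 1",
    gBlock3 = "Firmicutes", gBlock4 = "Deltaproteobacteria",
    gBlock5 = "Nitrospirae", gBlock6 = "Firmicutes",
    gBlock7 = "Environmental cluster 1", gBlock8 = "Deltaproteobacteria",
    gBlock9 = "Nitrospirae", gBlock10 = "Archaeoglobus",
    gBlock11 = "Deltaproteobacteria", gBlock12 = "Firmicutes"
  )
  list(members = members, one_mm = one_mm, supercluster = supercluster)
}

# Start positions (0-based) of each implanted site on the 390 bp fragment.
.dsrb_site_starts <- c(A_f = 25L, B_f = 55L, C_f = 85L,
                       C_r = 270L, B_r = 300L, A_r = 330L)

#' Synthetic dsrB gBlock template panel
#'
#' Twelve 390 bp double-stranded DNA fragments (gBlocks) spanning the five
#' dsrAB phylogenetic superclusters of sulfate reducers. The sequences are
#' synthetic stand-ins (seeded random backbones with implanted primer
#' binding sites), constructed so that at a 1-mismatch tolerance the three
#' [dsrb_primer_sets()] assays amplify 7, 8 and 9 of the 12 gBlocks
#' respectively, four gBlocks are amplifiable by all three assays
#' ("common"), four by exactly two ("less common") and four by exactly one
#' ("rare"). gBlock 3 binds the DSR1762Fmix/DSR2107Rmix assay with one
#' forward-primer mismatch and gBlock 7 the DSR1728Fmix/DSR4Rmix assay
#' likewise; every other implanted site is a perfect match.
#'
#' @return Named list of twelve [template_seq()] objects.
#' @export
dsrb_gblocks <- function() {
  panel <- .dsrb_panel()
  implants <- .dsrb_implants()
  starts <- .dsrb_site_starts
  out <- vector("list", length(panel$members))
  names(out) <- names(panel$members)
  for (k in seq_along(panel$members)) {
    id <- names(panel$members)[k]
    backbone <- with_preserved_rng(
      20260900L + k,
      sample(c("A", "C", "G", "T"), 390, replace = TRUE)
    )
    for (set in panel$members[[id]]) {
      for (side in c("f", "r")) {
        site <- paste0(set, "_", side)
        oligo <- strsplit(implants[[site]], "")[[1]]
        if (identical(panel$one_mm[[id]], site)) {
          # corrupt one internal position to create a single mismatch
          pos <- 5L
          oligo[pos] <- setdiff(c("A", "C", "G", "T"), oligo[pos])[1]
        }
        idx <- seq.int(starts[[site]] + 1L, starts[[site]] + length(oligo))
        backbone[idx] <- oligo
      }
    }
    out[[id]] <- template_seq(id, paste(backbone, collapse = ""),
                              supercluster_label = panel$supercluster[[id]])
  }
  out
}

#' Per-template amplification-efficiency overrides emulating assay-specific
#' poor amplification
#'
#' The default efficiency model assigns one per-cycle efficiency per
#' mismatch category, but empirically the amplification performance of a
#' template is not always reflected by its mismatch count. This packaged
#' scenario gives the dominant rare-panel gBlocks 3, 6 and 7 poor per-cycle
#' efficiencies under the degenerate assays (recoveries of a few percent of
#' input over a full run), emulating idiosyncratic single-template
#' performance.
#'
#' @return data.frame with columns `template_id`, `primer_set`, `efficiency`.
#' @export
dsrb_efficiency_overrides <- function() {
  data.frame(
    template_id = c("gBlock3", "gBlock6", "gBlock7"),
    primer_set = c("DSR1762Fmix/DSR2107Rmix", "DSR1728Fmix/DSR4Rmix",
                   "DSR1728Fmix/DSR4Rmix"),
    efficiency = c(0.60, 0.55, 0.50),
    stringsAsFactors = FALSE
  )
}

#' Canonical within-group dominance priorities for the dsrB study design
#'
#' Fixes which templates carry the top abundance ranks inside each
#' amplifiability group, emulating a fixed mixture-design table: in
#' rare-dominated mixtures gBlocks 3, 6 and 7 (bound only by the degenerate
#' assays) carry the largest fractions.
#'
#' @return Named list of character vectors (`common`, `"less common"`, `rare`).
#' @export
dsrb_dominance_priority <- function() {
  list(
    common = c("gBlock4", "gBlock5", "gBlock8", "gBlock11"),
    `less common` = c("gBlock12", "gBlock9", "gBlock10", "gBlock1"),
    rare = c("gBlock3", "gBlock6", "gBlock7", "gBlock2")
  )
}

#' Assembled synthetic dsrB reference
#'
#' Bundles the assay panel, gBlock panel, the amplifiability matrix at the
#' conventional 1-mismatch tolerance, the canonical dominance priorities and
#' the packaged efficiency overrides.
#'
#' @return List with elements `primer_sets`, `templates`, `amplifiability`,
#'   `priority`, `overrides`.
#' @export
dsrb_reference <- function() {
  psets <- dsrb_primer_sets()
  templates <- dsrb_gblocks()
  amat <- amplifiability_matrix(templates, psets, max_mm = 1L)
  for (id in names(templates)) {
    templates[[id]]$group_label <- unname(amat$groups[id])
  }
  list(primer_sets = psets, templates = templates, amplifiability = amat,
       priority = dsrb_dominance_priority(), overrides = dsrb_efficiency_overrides())
}

#' Read templates from a FASTA file
#'
#' @param path FASTA path; record names become template ids.
#' @return Named list of [template_seq()] objects.
#' @export
read_template_fasta <- function(path) {
  seqs <- Biostrings::readDNAStringSet(path)
  out <- lapply(seq_along(seqs), function(i) {
    template_seq(names(seqs)[i], as.character(seqs[[i]]))
  })
  names(out) <- names(seqs)
  out
}

#' Read primer sets from a FASTA file
#'
#' Headers follow the convention `>name|set|F` or `>name|set|R`; records
#' sharing a `set` field are grouped into one assay with forward (`F`) and
#' reverse (`R`) mixes.
#'
#' @param path FASTA path.
#' @return Named list of [primer_set()] objects.
#' @export
read_primer_fasta <- function(path) {
  seqs <- Biostrings::readDNAStringSet(path)
  fields <- strsplit(names(seqs), "|", fixed = TRUE)
  bad <- which(lengths(fields) != 3L)
  if (length(bad) > 0L) {
    stop("primer FASTA header must be 'name|set|F/R' (record ", bad[1], ")",
         call. = FALSE)
  }
  info <- data.frame(
    name = vapply(fields, `[[`, character(1), 1L),
    set = vapply(fields, `[[`, character(1), 2L),
    dir = vapply(fields, `[[`, character(1), 3L),
    seq = as.character(seqs),
    stringsAsFactors = FALSE
  )
  if (!all(info$dir %in% c("F", "R"))) {
    stop("primer orientation field must be 'F' or 'R'", call. = FALSE)
  }
  out <- lapply(split(info, info$set), function(d) {
    primer_set(
      d$set[1],
      forward_mix = lapply(which(d$dir == "F"), function(i)
        degenerate_primer(d$name[i], d$seq[i], "forward")),
      reverse_mix = lapply(which(d$dir == "R"), function(i)
        degenerate_primer(d$name[i], d$seq[i], "reverse"))
    )
  })
  out[unique(info$set)]
}

#' Write templates or primer sets to FASTA
#'
#' @param templates Named list of [template_seq()] objects.
#' @param path Output path.
#' @return `path`, invisibly.
#' @export
write_template_fasta <- function(templates, path) {
  seqs <- Biostrings::DNAStringSet(
    vapply(templates, `[[`, character(1), "sequence"))
  names(seqs) <- vapply(templates, `[[`, character(1), "id")
  Biostrings::writeXStringSet(seqs, path)
  invisible(path)
}

#' @rdname write_template_fasta
#' @param primer_sets Named list of [primer_set()] objects.
#' @export
write_primer_fasta <- function(primer_sets, path) {
  recs <- character(0)
  hdrs <- character(0)
  for (ps in primer_sets) {
    for (p in ps$forward_mix) {
      hdrs <- c(hdrs, paste(p$name, ps$name, "F", sep = "|"))
      recs <- c(recs, p$sequence)
    }
    for (p in ps$reverse_mix) {
      hdrs <- c(hdrs, paste(p$name, ps$name, "R", sep = "|"))
      recs <- c(recs, p$sequence)
    }
  }
  seqs <- Biostrings::DNAStringSet(recs)
  names(seqs) <- hdrs
  Biostrings::writeXStringSet(seqs, path)
  invisible(path)
}
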