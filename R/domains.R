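#' Protein domain map
#'
#' Maps 1-based residue indices to named protein domains. Each entry
#' carries a label, a residue span and a category (`n_term`,
#' `zinc_finger`, `c_term`, `motif`). Zinc-finger entries additionally
#' carry the indices of their two zinc-coordinating cysteines and two
#' histidines plus the recognition-helix anchor residue (helix position
#' +1); DNA-contact residues are the offsets -1, +2, +3 and +6 from
#' that anchor.
#'
#' @param entries `data.frame` with columns `label`, `aa_start`,
#'   `aa_end`, `category`, and optional `cys` / `his` (comma-separated
#'   residue indices), `helix_anchor`, `rbd` (logical: span carries an
#'   RNA-binding domain), `verified` (logical).
#' @param protein_length Total protein length in residues.
#' @return Object of class `domain_map`.
#' @export
domain_map <- function(entries, protein_length) {
  entries <- as.data.frame(entries)
  need <- c("label", "aa_start", "aa_end", "category")
  stopifnot(all(need %in% names(entries)))
  for (opt in c("cys", "his")) if (!opt %in% names(entries)) entries[[opt]] <- ""
  if (!"helix_anchor" %in% names(entries)) entries$helix_anchor <- NA_integer_
  if (!"rbd" %in% names(entries)) entries$rbd <- FALSE
  if (!"verified" %in% names(entries)) entries$verified <- TRUE
  stopifnot(all(entries$aa_start <= entries$aa_end),
            all(entries$aa_end <= protein_length),
            all(entries$category %in% c("n_term", "zinc_finger", "c_term", "motif")))
  parse_idx <- function(s) {
    if (is.na(s) || !nzchar(s)) return(integer(0))
    as.integer(strsplit(s, ",", fixed = TRUE)[[1]])
  }
  for (i in seq_len(nrow(entries))) {
    if (entries$category[i] == "zinc_finger" && isTRUE(entries$verified[i])) {
      cys <- parse_idx(entries$cys[i]); his <- parse_idx(entries$his[i])
      if (length(cys) != 2 || length(his) != 2) {
        stop("zinc-finger entry ", entries$label[i],
             " must carry exactly 2 Cys and 2 His coordinating indices")
      }
      idx <- c(cys, his)
      if (any(idx < entries$aa_start[i] | idx > entries$aa_end[i])) {
        stop("coordinating residues of ", entries$label[i],
             " fall outside its span")
      }
    }
  }
  structure(list(entries = entries, protein_length = as.integer(protein_length)),
            class = "domain_map")
}

.dm_indices <- function(s) {
  if (is.na(s) || !nzchar(s)) integer(0) else as.integer(strsplit(s, ",")[[1]])
}

#' Domain label of a residue
#'
#' @param map A [domain_map()].
#' @param residue 1-based residue index.
#' @return Label of the covering entry, or `"linker"` when the residue
#'   lies between zinc fingers, `"none"` otherwise.
#' @export
domain_of <- function(map, residue) {
  stopifnot(inherits(map, "domain_map"))
  residue <- as.integer(residue)
  if (is.na(residue) || residue < 1 || residue > map$protein_length) {
    stop("residue ", residue, " out of protein range 1-", map$protein_length)
  }
  e <- map$entries
  hit <- which(e$aa_start <= residue & residue <= e$aa_end)
  if (length(hit)) {
    # prefer the most specific entry: motif > zinc_finger > termini
    pref <- match(e$category[hit], c("motif", "zinc_finger", "n_term", "c_term"))
    return(e$label[hit[which.min(pref)]])
  }
  zf <- e[e$category == "zinc_finger", ]
  if (nrow(zf) && residue > min(zf$aa_start) && residue < max(zf$aa_end)) {
    return("linker")
  }
  "none"
}

#' Functional role of a residue
#'
#' Roles, in decreasing precedence: zinc-coordinating Cys/His (explicit
#' per-finger indices), DNA-contact (helix offsets -1/+2/+3/+6), the
#' YDF cohesin-retention motif, RNA-binding-domain spans, zinc-finger
#' linker, or none.
#'
#' @inheritParams domain_of
#' @return One of `"zinc_coordinating_cys"`, `"zinc_coordinating_his"`,
#'   `"dna_contact"`, `"ydf"`, `"rbd"`, `"linker"`, `"none"`.
#' @export
residue_role <- function(map, residue) {
  stopifnot(inherits(map, "domain_map"))
  residue <- as.integer(residue)
  if (is.na(residue) || residue < 1 || residue > map$protein_length) {
    stop("residue ", residue, " out of protein range 1-", map$protein_length)
  }
  e <- map$entries
  for (i in seq_len(nrow(e))) {
    if (residue %in% .dm_indices(e$cys[i])) return("zinc_coordinating_cys")
    if (residue %in% .dm_indices(e$his[i])) return("zinc_coordinating_his")
  }
  for (i in which(!is.na(e$helix_anchor))) {
    if ((residue - e$helix_anchor[i]) %in% c(-1L, 2L, 3L, 6L) &&
        residue >= e$aa_start[i] - 1 && residue <= e$aa_end[i] + 6) {
      return("dna_contact")
    }
  }
  lab <- domain_of(map, residue)
  row <- match(lab, e$label)
  if (!is.na(row)) {
    if (e$category[row] == "motif" && toupper(lab) == "YDF") return("ydf")
    if (isTRUE(e$rbd[row])) return("rbd")
  }
  if (identical(lab, "linker")) return("linker")
  "none"
}

#' Default CTCF domain map
#'
#' Carries only the entries whose residue spans are established in the
#' literature on the 726-residue protein: the YDF cohesin-retention
#' motif (226-228), ZF1 (264-275, RNA-binding) and ZF10 (536-544,
#' RNA-binding), plus N- and C-terminal spans. ZF1/ZF10 rows are
#' flagged `verified = FALSE` because their zinc-coordinating Cys/His
#' indices and helix anchors are not pinned here. The remaining fingers
#' (ZF2-ZF9, ZF11) are deliberately absent: exact spans must come from
#' a user-supplied domain config, never guessed.
#'
#' @return A [domain_map()] over 726 residues.
#' @export
ctcf_domains <- function() {
  entries <- data.frame(
    label = c("N_term", "YDF", "ZF1", "ZF10", "C_term"),
    aa_start = c(1L, 226L, 264L, 536L, 584L),
    aa_end = c(263L, 228L, 275L, 544L, 726L),
    category = c("n_term", "motif", "zinc_finger", "zinc_finger", "c_term"),
    cys = "", his = "", helix_anchor = NA_integer_,
    rbd = c(FALSE, FALSE, TRUE, TRUE, FALSE),
    verified = c(TRUE, TRUE, FALSE, FALSE, TRUE),
    stringsAsFactors = FALSE
  )
  domain_map(entries, protein_length = 726L)
}
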