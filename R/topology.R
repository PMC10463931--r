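#' @keywords internal
"_PACKAGE"

# Elements with PEOE parameters; topology construction rejects anything else.
DDPD_ELEMENTS <- c("H", "C", "N", "O", "S", "F", "P", "Cl", "Br", "I")

#' Peptide-backbone residue template
#'
#' A minimal residue template (N, CA, C, O, H) used by [synth_topology()].
#' Local bond indices are 1-based within the residue; `link` gives the
#' (previous-residue atom, this-residue atom) pair bonded across consecutive
#' residues (the peptide C-N bond). The carbonyl C=O carries bond order 2 so
#' that charge computation sees sp2 centres.
#'
#' @return A list with elements `atoms` (data.frame: `name`, `element`),
#'   `bonds` (data.frame: `i`, `j`, `order`, local 1-based) and `link`.
#' @export
backbone_template <- function() {
  list(
    atoms = data.frame(
      name = c("N", "CA", "C", "O", "H"),
      element = c("N", "C", "C", "O", "H"),
      stringsAsFactors = FALSE
    ),
    bonds = data.frame(
      i = c(1L, 2L, 3L, 1L),
      j = c(2L, 3L, 4L, 5L),
      order = c(1L, 1L, 2L, 1L)
    ),
    link = c(3L, 1L) # C(i-1) - N(i)
  )
}

#' Single-carbon residue template
#'
#' One carbon per residue, linked in a chain (and optionally closed into a
#' ring by [synth_topology()] via `cyclic = TRUE`). With every atom in an
#' identical environment all PEOE charges are equal, which keeps the charge
#' channel inert in spectrum-controlled fixtures.
#'
#' @return A template list as in [backbone_template()]. The single atom is
#'   named "CA" so that per-residue RMSF remains computable.
#' @export
carbon_template <- function() {
  list(
    atoms = data.frame(name = "CA", element = "C", stringsAsFactors = FALSE),
    bonds = data.frame(i = integer(), j = integer(), order = integer()),
    link = c(1L, 1L)
  )
}

#' Build a synthetic protein topology
#'
#' Replicates a residue template `n_residues` times, wiring consecutive
#' residues through the template's link bond. Atom and residue indices are
#' 0-based internally; author residue numbering is 1-based.
#'
#' @param n_residues Number of residues (>= 1).
#' @param template Residue template, see [backbone_template()].
#' @param resname Three-letter residue name used for every residue.
#' @param cyclic If `TRUE`, also bond the last residue back to the first
#'   (used by all-carbon ring fixtures so no atom is terminal).
#' @return A `ddpd_topology`: list with `atoms` (data.frame: `index`,
#'   `element`, `name`, `resindex`, `resname`, `resno`) and `bonds`
#'   (data.frame of 0-based `i`, `j` plus `order`).
#' @export
synth_topology <- function(n_residues, template = backbone_template(),
                           resname = "GLY", cyclic = FALSE) {
  stopifnot(n_residues >= 1)
  ta <- template$atoms
  if (!all(ta$element %in% DDPD_ELEMENTS)) {
    stop("unknown element symbol: ",
         paste(setdiff(ta$element, DDPD_ELEMENTS), collapse = ", "))
  }
  k <- nrow(ta)
  n_at <- n_residues * k
  atoms <- data.frame(
    index = seq_len(n_at) - 1L,
    element = rep(ta$element, n_residues),
    name = rep(ta$name, n_residues),
    resindex = rep(seq_len(n_residues) - 1L, each = k),
    resname = resname,
    resno = rep(seq_len(n_residues), each = k),
    stringsAsFactors = FALSE
  )
  bl <- list()
  for (r in seq_len(n_residues)) {
    off <- (r - 1L) * k
    if (nrow(template$bonds) > 0) {
      bl[[length(bl) + 1L]] <- data.frame(
        i = template$bonds$i + off - 1L,
        j = template$bonds$j + off - 1L,
        order = template$bonds$order
      )
    }
    if (r > 1L) {
      bl[[length(bl) + 1L]] <- data.frame(
        i = template$link[1] + (r - 2L) * k - 1L,
        j = template$link[2] + off - 1L,
        order = 1L
      )
    }
  }
  if (cyclic && n_residues > 2L) {
    bl[[length(bl) + 1L]] <- data.frame(
      i = template$link[1] + (n_residues - 1L) * k - 1L,
      j = template$link[2] - 1L, order = 1L
    )
  }
  bonds <- if (length(bl)) do.call(rbind, bl) else
    data.frame(i = integer(), j = integer(), order = integer())
  validate_bonds(bonds, n_at)
  structure(list(atoms = atoms, bonds = bonds), class = "ddpd_topology")
}

validate_bonds <- function(bonds, n_atoms) {
  if (nrow(bonds) && (any(bonds$i < 0 | bonds$i >= n_atoms) ||
                      any(bonds$j < 0 | bonds$j >= n_atoms))) {
    stop("bond references a missing atom")
  }
  invisible(TRUE)
}

#' @export
print.ddpd_topology <- function(x, ...) {
  cat("ddpd_topology:", nrow(x$atoms), "atoms,",
      length(unique(x$atoms$resindex)), "residues,",
      nrow(x$bonds), "bonds\n")
  invisible(x)
}

n_atoms <- function(topology) nrow(topology$atoms)
n_residues <- function(topology) length(unique(topology$atoms$resindex))

# 0-based atom indices of each residue, in residue order.
residue_atoms <- function(topology) {
  split(topology$atoms$index, topology$atoms$resindex)
}

# 0-based indices of the CA atom per residue; errors if any residue lacks one.
ca_indices <- function(topology) {
  a <- topology$atoms
  ca <- a[a$name == "CA", ]
  res <- sort(unique(a$resindex))
  if (!setequal(ca$resindex, res) || anyDuplicated(ca$resindex)) {
    stop("every residue must have exactly one CA atom")
  }
  ca$index[order(ca$resindex)]
}
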