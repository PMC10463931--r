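# Non-dynamic comparison descriptors: per-residue scale one-hot encodings
# mapped onto the MSA, and folded circular (Morgan) fingerprints for
# compounds.

#' Available residue scale tables
#'
#' Embedded plain-text tables (see `inst/extdata/scales/`):
#' `zscale_hellberg` -- the five-component z-scales (extended z-scale set of
#' Sandberg et al. 1998); `zscale_vanwesten` -- the three-component z-scales
#' (Hellberg et al. 1987); `mswhim` -- three MS-WHIM scores per residue
#' (Zaliani & Gancia 1999); `physchem` -- five standard physicochemical
#' constants per residue (Kyte-Doolittle hydropathy, average residue mass,
#' net charge at pH 7, side-chain H-bond donor count, aromaticity flag).
#'
#' @return Character vector of scale names.
#' @export
residue_scale_names <- function() {
  c("zscale_hellberg", "zscale_vanwesten", "mswhim", "physchem")
}

#' Load a residue scale table
#'
#' @param name One of [residue_scale_names()].
#' @return A `ddpd_scale`: list with `name`, `d` (values per residue) and
#'   `values` (20 x d matrix, rownames = one-letter amino-acid codes).
#' @export
residue_scale <- function(name) {
  name <- match.arg(name, residue_scale_names())
  path <- system.file("extdata", "scales", paste0(name, ".csv"),
                      package = "ddpd3", mustWork = TRUE)
  tab <- utils::read.csv(path, stringsAsFactors = FALSE)
  values <- as.matrix(tab[, -1, drop = FALSE])
  rownames(values) <- tab$aa
  stopifnot(nrow(values) == 20)
  structure(list(name = name, d = ncol(values), values = values),
            class = "ddpd_scale")
}

#' One-hot residue scale descriptor over an MSA
#'
#' Position-major layout identical to the residue-specific dynamic
#' descriptors: `d` features per alignment column, the target's residue
#' values at its mapped columns and zero blocks at its gap columns.
#'
#' @param msa A `ddpd_msa`.
#' @param target_id Target identifier.
#' @param table A `ddpd_scale` from [residue_scale()].
#' @return Named numeric vector of length `d * L` (`AA{col}_{property}`).
#' @export
scale_descriptor <- function(msa, target_id, table) {
  map <- msa_map_of(msa, target_id)
  row <- strsplit(msa$rows[[target_id]], "")[[1]]
  res <- row[map]
  bad <- setdiff(res, rownames(table$values))
  if (length(bad)) stop("non-standard residue code: ",
                        paste(unique(bad), collapse = ", "))
  d <- table$d
  L <- msa$L
  values <- numeric(d * L)
  names(values) <- paste0("AA", rep(seq_len(L), each = d), "_",
                          rep(colnames(table$values), L))
  for (i in seq_along(map)) {
    values[(map[i] - 1L) * d + seq_len(d)] <- table$values[res[i], ]
  }
  values
}

# default valences for implicit-hydrogen inference on neutral molecules
default_valence <- c(H = 1, C = 4, N = 3, O = 2, S = 2, P = 3,
                     F = 1, Cl = 1, Br = 1, I = 1)

smiles_graph <- function(smiles) {
  can <- tryCatch(
    ChemmineOB::convertFormat("SMI", "CAN", source = smiles),
    error = function(e) ""
  )
  can <- sub("\\s.*$", "", trimws(can))
  if (!nzchar(can)) stop("unparsable SMILES: ", smiles)
  # single-atom molecules: ChemmineR cannot represent a zero-bond SDF
  solo <- regmatches(can, regexec("^\\[?([A-Z][a-z]?)H?[0-9]*\\]?$", can))[[1]]
  if (length(solo) == 2 && solo[2] %in% names(default_valence)) {
    return(list(elements = solo[2],
                bonds = data.frame(i = integer(), j = integer(),
                                   order = integer())))
  }
  sdf <- suppressWarnings(ChemmineR::smiles2sdf(can))[[1]]
  ab <- ChemmineR::atomblock(sdf)
  bb <- ChemmineR::bondblock(sdf)
  elements <- sub("_.*$", "", rownames(ab))
  # bond-free molecules yield a placeholder zero row / short block
  bonds <- if (is.null(dim(bb)) || nrow(bb) == 0 || ncol(bb) < 3) {
    data.frame(i = integer(), j = integer(), order = integer())
  } else {
    data.frame(i = as.integer(bb[, 1]), j = as.integer(bb[, 2]),
               order = as.integer(bb[, 3]))
  }
  bonds <- bonds[bonds$i > 0 & bonds$j > 0, , drop = FALSE]
  list(elements = elements, bonds = bonds)
}

# deterministic integer hash of an integer vector (mod 2^31 - 1)
hash_ints <- function(v) {
  h <- 17
  for (x in v) h <- (h * 31 + (x %% 2147483647) + 1) %% 2147483647
  as.integer(h)
}

#' Folded circular fingerprint (ECFP-style) from SMILES
#'
#' Morgan-style iterative neighbourhood hashing of radius `radius` on the
#' heavy-atom graph (SMILES are canonicalized first, so different writings
#' of one molecule give one fingerprint), folded to `n_bits` binary bits.
#' Initial atom invariants are atomic number, heavy degree, bond-order sum
#' and implicit hydrogen count. Hashing is backend-specific: fingerprints
#' are deterministic within this package but not bit-compatible with other
#' toolkits.
#'
#' @param smiles A SMILES string.
#' @param n_bits Fingerprint length (default 1024).
#' @param radius Neighbourhood radius (default 3, i.e. ECFP6).
#' @return Integer 0/1 vector of length `n_bits`.
#' @export
ecfp6 <- function(smiles, n_bits = 1024, radius = 3) {
  g <- smiles_graph(smiles)
  n <- length(g$elements)
  z <- c(H = 1, C = 6, N = 7, O = 8, F = 9, P = 15, S = 16,
         Cl = 17, Br = 35, I = 53)[g$elements]
  if (any(is.na(z))) stop("unsupported element in SMILES: ", smiles)
  nbrs <- lapply(seq_len(n), function(i) {
    rbind(
      cbind(g$bonds$order[g$bonds$i == i], g$bonds$j[g$bonds$i == i]),
      cbind(g$bonds$order[g$bonds$j == i], g$bonds$i[g$bonds$j == i])
    )
  })
  ordsum <- vapply(nbrs, function(m) sum(m[, 1]), numeric(1))
  degree <- vapply(nbrs, nrow, integer(1))
  hcount <- pmax(0, default_valence[g$elements] - ordsum)
  ids <- vapply(seq_len(n), function(i) {
    hash_ints(c(z[i], degree[i], ordsum[i], hcount[i]))
  }, integer(1))
  all_ids <- ids
  for (r in seq_len(radius)) {
    ids <- vapply(seq_len(n), function(i) {
      m <- nbrs[[i]]
      env <- if (nrow(m)) {
        pairs <- cbind(m[, 1], ids[m[, 2]])
        pairs <- pairs[order(pairs[, 1], pairs[, 2]), , drop = FALSE]
        as.vector(t(pairs))
      } else integer()
      hash_ints(c(r, ids[i], env))
    }, integer(1))
    all_ids <- c(all_ids, ids)
  }
  bits <- integer(n_bits)
  bits[unique(all_ids %% n_bits) + 1L] <- 1L
  bits
}

#' Fingerprint a set of SMILES
#'
#' @param smiles Character vector of SMILES.
#' @param n_bits,radius Passed to [ecfp6()].
#' @return Integer matrix, one row per SMILES (rownames = SMILES), columns
#'   `fp1..fp{n_bits}`.
#' @export
ecfp6_matrix <- function(smiles, n_bits = 1024, radius = 3) {
  u <- unique(smiles)
  m <- t(vapply(u, ecfp6, integer(n_bits), n_bits = n_bits, radius = radius))
  colnames(m) <- paste0("fp", seq_len(n_bits))
  rownames(m) <- u
  m
}
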