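#' Descriptor rule-set identifiers
#'
#' The exact conventions a fitted profile was built with. Scoring refuses a
#' profile whose conventions differ from these, so descriptors are never mixed
#' across rule sets.
#'
#' @return Named character vector of convention identifiers.
#' @export
descriptor_conventions <- function() {
  c(mw    = "sum of standard atomic weights, implicit H included (OpenBabel)",
    logp  = "Wildman-Crippen atomic contribution logP (OpenBabel)",
    hba   = "count of N and O atoms (SMARTS [#7,#8])",
    hbd   = "count of N or O atoms bearing >= 1 H (SMARTS [#7,#8;!H0])",
    nrotb = "non-ring single bonds between non-terminal heavy atoms, amide C-N excluded",
    narr  = "aromatic count of smallest rings (ChemmineR inner-ring perception)",
    salts = "largest covalent fragment by heavy-atom count, ties to first")
}

qea_descriptors <- c("mw", "logp", "hba", "hbd", "nrotb", "narr")

#' Compute the six QEA molecular descriptors
#'
#' Adds molecular weight (g/mol), Wildman-Crippen logP, hydrogen-bond
#' acceptor and donor counts, rotatable-bond count and aromatic-ring count to
#' a compound table. Multi-fragment inputs (salts, mixtures) are reduced to
#' their largest covalent fragment first; the fragment actually used is
#' reported in `fragment_smiles` with `salt_stripped = TRUE`. Invalid
#' compounds keep their row with `NA` descriptors.
#'
#' Descriptor values are deterministic for a given SMILES and identical for
#' any two SMILES that canonicalise to the same structure.
#'
#' @param compounds Compound tibble from [read_compounds()] or
#'   [compound_tbl()].
#' @return The input tibble plus columns `mw`, `logp`, `hba`, `hbd`, `nrotb`,
#'   `narr`, `canonical_smiles`, `fragment_smiles`, `salt_stripped`.
#' @examples
#' \dontrun{
#' compound_tbl("c1ccccc1", "benzene") |> compute_descriptors()
#' }
#' @export
compute_descriptors <- function(compounds) {
  check_compound_tbl(compounds)
  n <- nrow(compounds)
  out <- dplyr::as_tibble(compounds)
  num_cols <- c(qea_descriptors, "salt_stripped")
  for (col in qea_descriptors) out[[col]] <- NA_real_
  out$canonical_smiles <- NA_character_
  out$fragment_smiles <- NA_character_
  out$salt_stripped <- FALSE

  idx <- which(out$valid)
  if (length(idx) == 0) return(out)

  frag <- vapply(out$smiles[idx], largest_fragment, "", USE.NAMES = FALSE)
  out$fragment_smiles[idx] <- frag
  out$salt_stripped[idx] <- frag != out$smiles[idx]

  # descriptors are computed on the canonical SMILES so that any two
  # spellings of one structure give bit-identical values
  can <- canonical_smiles(frag)
  can[is.na(can)] <- frag[is.na(can)]
  out$canonical_smiles[idx] <- can

  nm <- paste0("q", idx)
  smi <- stats::setNames(can, nm)
  sdf <- suppressWarnings(ChemmineR::smiles2sdf(smi))
  with_bonds <- ChemmineR::validSDF(sdf)

  if (any(with_bonds)) {
    sub <- sdf[which(with_bonds)]
    rows <- idx[match(ChemmineR::cid(sub), nm)]
    props <- ChemmineR::propOB(sub)
    rings <- ChemmineR::rings(sub, type = "count", arom = TRUE, inner = TRUE)
    if (is.null(dim(rings))) {
      rings <- matrix(rings, nrow = 1, dimnames = list(NULL, names(rings)))
    }
    out$mw[rows] <- props$MW
    out$logp[rows] <- props$logP
    out$hba[rows] <- ChemmineR::smartsSearchOB(sub, "[#7,#8]",
                                               uniqueMatches = TRUE)
    out$hbd[rows] <- ChemmineR::smartsSearchOB(sub, "[#7,#8;!H0]",
                                               uniqueMatches = TRUE)
    out$narr[rows] <- rings[, "AROMATIC"]
    out$nrotb[rows] <- vapply(seq_along(sub),
                              function(i) count_rotatable_bonds(sub[[i]]),
                              numeric(1))
  }

  # bondless molecules (single heavy atom) break the SDF round-trip;
  # their graph descriptors are trivially zero and H-bond counts follow
  # directly from the formula
  lone <- ChemmineR::cid(sdf)[!with_bonds]
  for (q in lone) {
    row <- idx[match(q, nm)]
    p <- ChemmineOB::forEachMol("SMILES", smi[[q]],
                                function(m) ChemmineOB::prop_OB(m))[[1]]
    elems <- regmatches(p$formula, gregexpr("[A-Z][a-z]?", p$formula))[[1]]
    is_no <- any(elems %in% c("N", "O"))
    has_h <- "H" %in% elems
    out$mw[row] <- p$MW
    out$logp[row] <- p$logP
    out$hba[row] <- as.numeric(is_no)
    out$hbd[row] <- as.numeric(is_no && has_h)
    out$narr[row] <- 0
    out$nrotb[row] <- 0
    out$canonical_smiles[row] <- p$cansmi
  }
  out
}

# Largest covalent fragment of a (possibly dotted) SMILES, by heavy-atom
# count estimated from element symbols; ties keep the first fragment.
largest_fragment <- function(smiles) {
  if (!grepl(".", smiles, fixed = TRUE)) return(smiles)
  frags <- strsplit(smiles, ".", fixed = TRUE)[[1]]
  frags <- frags[nzchar(frags)]
  if (length(frags) == 1) return(frags)
  sizes <- vapply(frags, heavy_atoms_in_smiles, numeric(1))
  frags[which.max(sizes)]
}

heavy_atoms_in_smiles <- function(smiles) {
  m <- regmatches(smiles,
    gregexpr("\\[[^]]*\\]|Cl|Br|Si|Se|As|[BCNOPSFI]|[cnosp]", smiles))[[1]]
  if (length(m) == 0) return(0)
  explicit_h <- grepl("^\\[[0-9]*H[0-9]*[+-]?\\]$", m)
  sum(!explicit_h)
}

# Rotatable bonds on the heavy-atom graph of one molecule:
# single, not in a ring, neither end terminal, amide C-N excluded.
count_rotatable_bonds <- function(sdf_mol) {
  bb <- ChemmineR::bondblock(sdf_mol)
  if (is.null(dim(bb)) || nrow(bb) == 0) return(0)
  ab <- ChemmineR::atomblock(sdf_mol)
  sym <- sub("_.*$", "", rownames(ab))
  heavy <- sym != "H"
  a1 <- bb[, 1]; a2 <- bb[, 2]; order <- bb[, 3]

  keep <- heavy[a1] & heavy[a2]
  a1 <- a1[keep]; a2 <- a2[keep]; order <- order[keep]
  if (length(a1) == 0) return(0)

  deg <- tabulate(c(a1, a2), nbins = nrow(ab))
  in_ring <- ring_bond_flags(a1, a2, nrow(ab))

  amide <- mapply(function(i, j) {
    is_amide_cn(i, j, sym, a1, a2, order)
  }, a1, a2)

  sum(order == 1 & !in_ring & deg[a1] > 1 & deg[a2] > 1 & !amide)
}

# A bond is part of a ring iff it is not a bridge of the heavy-atom graph.
ring_bond_flags <- function(a1, a2, n_atoms) {
  m <- length(a1)
  flags <- logical(m)
  for (k in seq_len(m)) {
    flags[k] <- connected_without_edge(a1, a2, k, a1[k], a2[k], n_atoms)
  }
  flags
}

connected_without_edge <- function(a1, a2, drop, from, to, n_atoms) {
  adj <- vector("list", n_atoms)
  for (k in seq_along(a1)) {
    if (k == drop) next
    adj[[a1[k]]] <- c(adj[[a1[k]]], a2[k])
    adj[[a2[k]]] <- c(adj[[a2[k]]], a1[k])
  }
  seen <- logical(n_atoms)
  stack <- from
  seen[from] <- TRUE
  while (length(stack) > 0) {
    v <- stack[[length(stack)]]
    stack <- stack[-length(stack)]
    if (v == to) return(TRUE)
    nb <- adj[[v]]
    new <- nb[!seen[nb]]
    seen[new] <- TRUE
    stack <- c(stack, new)
  }
  FALSE
}

# amide C-N: a single C-N bond whose carbon carries a double bond to oxygen
is_amide_cn <- function(i, j, sym, a1, a2, order) {
  pair <- sort(c(sym[i], sym[j]))
  if (!identical(pair, c("C", "N"))) return(FALSE)
  carbon <- if (sym[i] == "C") i else j
  hit <- (a1 == carbon & sym[a2] == "O" & order == 2) |
         (a2 == carbon & sym[a1] == "O" & order == 2)
  any(hit)
}

#' Write a descriptor table to CSV
#'
#' @param descriptors Tibble from [compute_descriptors()].
#' @param path Output CSV path.
#' @return `path`, invisibly.
#' @export
write_descriptors <- function(descriptors, path) {
  cols <- c("id", "smiles", qea_descriptors, "valid")
  missing <- setdiff(cols, names(descriptors))
  if (length(missing) > 0) {
    stop("descriptor table lacks columns: ", paste(missing, collapse = ", "),
         call. = FALSE)
  }
  readr::write_csv(descriptors[, cols], path, progress = FALSE)
  invisible(path)
}
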