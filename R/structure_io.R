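#' Read a protein structure from a PDB file
#'
#' Parses ATOM/HETATM records (via \pkg{bio3d}), keeps the requested model,
#' removes waters and hydrogens, and resolves alternate locations by keeping
#' the highest-occupancy copy of each atom (ties go to the first occurrence
#' in the file).
#'
#' @param file Path to a PDB file, or a character vector of PDB-format lines
#'   (recognised when the input has more than one element or contains a
#'   newline).
#' @param model Model number to extract from a multi-model file (default 1).
#' @return An object of class \code{aak_structure}: a list with an
#'   \code{atom} data frame (one row per retained atom) and \code{nmodels}.
#' @export
read_structure <- function(file, model = 1) {
  if (length(file) > 1 || grepl("\n", file[1], fixed = TRUE)) {
    tmp <- tempfile(fileext = ".pdb")
    writeLines(unlist(strsplit(file, "\n", fixed = TRUE)), tmp)
    on.exit(unlink(tmp))
    file <- tmp
  }
  pdb <- tryCatch(
    bio3d::read.pdb(file, multi = TRUE, rm.alt = FALSE, verbose = FALSE),
    error = function(e) stopf("failed to parse PDB input: %s", conditionMessage(e))
  )
  atom <- pdb$atom
  xyz <- pdb$xyz
  nmodels <- if (is.matrix(xyz)) nrow(xyz) else 1L
  if (model < 1 || model > nmodels) {
    stopf("model %d not present (file has %d model(s))", model, nmodels)
  }
  if (model > 1) {
    m <- matrix(xyz[model, ], ncol = 3, byrow = TRUE)
    atom$x <- m[, 1]; atom$y <- m[, 2]; atom$z <- m[, 3]
  }
  bad <- which(!is.finite(atom$x) | !is.finite(atom$y) | !is.finite(atom$z))
  if (length(bad) > 0) {
    stopf("malformed coordinate fields for atom serial(s): %s",
          paste(utils::head(atom$eleno[bad], 5), collapse = ", "))
  }
  atom$chain[is.na(atom$chain) | atom$chain == ""] <- "A"
  atom$insert[is.na(atom$insert)] <- ""
  atom$alt[is.na(atom$alt)] <- ""
  atom$o[is.na(atom$o)] <- 1
  atom$b[is.na(atom$b)] <- 0

  ## drop waters and hydrogens/deuteriums
  atom <- atom[!(atom$resid %in% c("HOH", "WAT", "DOD", "H2O")), , drop = FALSE]
  elesy <- atom$elesy
  hyd <- !is.na(elesy) & elesy %in% c("H", "D")
  hyd[is.na(elesy)] <- grepl("^[0-9]*H", atom$elety[is.na(elesy)])
  atom <- atom[!hyd, , drop = FALSE]

  ## altloc: per (chain, resno, insert, atom name) keep the highest occupancy,
  ## ties resolved by file order
  if (any(atom$alt != "")) {
    key <- paste(atom$chain, atom$resno, atom$insert, atom$elety, sep = "|")
    ord <- order(key, -atom$o, seq_len(nrow(atom)))
    atom <- atom[ord, , drop = FALSE]
    atom <- atom[!duplicated(paste(atom$chain, atom$resno, atom$insert,
                                   atom$elety, sep = "|")), , drop = FALSE]
    atom <- atom[order(as.integer(rownames(atom))), , drop = FALSE]
  }
  if (nrow(atom) == 0) stopf("no residues after filtering")
  rownames(atom) <- NULL
  structure(list(atom = atom, nmodels = nmodels, model = as.integer(model)),
            class = "aak_structure")
}

#' @export
print.aak_structure <- function(x, ...) {
  a <- x$atom
  cat(sprintf("aak_structure: %d atoms, %d chain(s) [%s], model %d of %d\n",
              nrow(a), length(unique(a$chain)),
              paste(sort(unique(a$chain)), collapse = ","),
              x$model, x$nmodels))
  invisible(x)
}

#' Build the coarse-grained network model from a structure
#'
#' One node per standard amino-acid residue, represented by its C-alpha atom
#' and carrying the residue's heavy atoms and the C-alpha B-factor.
#' Optionally, one node per non-water hetero residue (ligand), represented by
#' its heavy-atom centroid. Node order is chain (in order of appearance),
#' then residue number, then insertion code; ligand nodes follow residue
#' nodes.
#'
#' @param struct An \code{aak_structure} from \code{\link{read_structure}}.
#' @param include_ligands Add hetero (non-water) residues as network nodes.
#' @param chains Optional character vector restricting to a chain subset.
#' @return A \code{coarse_model}: list with \code{label}, \code{kind}
#'   (\code{"residue"}/\code{"ligand"}), \code{chain}, \code{resno},
#'   \code{resid}, \code{xyz} (N x 3 representative coordinates, Angstrom),
#'   \code{b} (B-factors, NA when absent), \code{heavy} (list of per-node
#'   heavy-atom coordinate matrices) and \code{N}.
#' @export
build_coarse_model <- function(struct, include_ligands = FALSE, chains = NULL) {
  stopifnot(inherits(struct, "aak_structure"))
  atom <- struct$atom
  if (!is.null(chains)) {
    missing_ch <- setdiff(chains, unique(atom$chain))
    if (length(missing_ch) > 0) {
      stopf("chain(s) not present: %s", paste(missing_ch, collapse = ", "))
    }
    atom <- atom[atom$chain %in% chains, , drop = FALSE]
  }
  chain_order <- unique(atom$chain)
  atom$.chain_rank <- match(atom$chain, chain_order)

  split_residues <- function(a) {
    key <- paste(a$chain, a$resno, a$insert, sep = "|")
    idx <- split(seq_len(nrow(a)), key)
    ord <- order(vapply(idx, function(i) a$.chain_rank[i[1]], 0),
                 vapply(idx, function(i) a$resno[i[1]], 0),
                 vapply(idx, function(i) a$insert[i[1]], ""))
    idx[ord]
  }

  std <- atom[atom$type == "ATOM", , drop = FALSE]
  het <- atom[atom$type == "HETATM", , drop = FALSE]
  if (nrow(std) == 0 && !(include_ligands && nrow(het) > 0)) {
    stopf("no residues after filtering")
  }

  nodes <- list()
  if (nrow(std) > 0) {
    groups <- split_residues(std)
    no_ca <- character(0)
    for (ii in groups) {
      res <- std[ii, , drop = FALSE]
      ca <- which(res$elety == "CA")
      if (length(ca) == 0) {
        no_ca <- c(no_ca, sprintf("%s:%s%d%s", res$chain[1], res$resid[1],
                                  res$resno[1], res$insert[1]))
        next
      }
      ca <- ca[1]
      nodes[[length(nodes) + 1]] <- list(
        label = sprintf("%s:%s%d%s", res$chain[1], res$resid[1],
                        res$resno[1], res$insert[1]),
        kind = "residue", chain = res$chain[1], resno = res$resno[1],
        resid = res$resid[1],
        rep = c(res$x[ca], res$y[ca], res$z[ca]),
        b = res$b[ca],
        heavy = cbind(res$x, res$y, res$z))
    }
    if (length(no_ca) > 0) {
      stopf("residue(s) lacking a C-alpha atom: %s",
            paste(no_ca, collapse = ", "))
    }
  }
  if (include_ligands && nrow(het) > 0) {
    for (ii in split_residues(het)) {
      res <- het[ii, , drop = FALSE]
      xyz <- cbind(res$x, res$y, res$z)
      nodes[[length(nodes) + 1]] <- list(
        label = sprintf("%s:%s%d%s", res$chain[1], res$resid[1],
                        res$resno[1], res$insert[1]),
        kind = "ligand", chain = res$chain[1], resno = res$resno[1],
        resid = res$resid[1],
        rep = colMeans(xyz), b = NA_real_, heavy = xyz)
    }
  }
  if (length(nodes) < 2) stopf("coarse model needs at least 2 nodes, got %d",
                               length(nodes))
  new_coarse_model(
    label = vapply(nodes, `[[`, "", "label"),
    kind  = vapply(nodes, `[[`, "", "kind"),
    chain = vapply(nodes, `[[`, "", "chain"),
    resno = vapply(nodes, `[[`, 0, "resno"),
    resid = vapply(nodes, `[[`, "", "resid"),
    xyz   = do.call(rbind, lapply(nodes, `[[`, "rep")),
    b     = vapply(nodes, `[[`, 0, "b"),
    heavy = lapply(nodes, `[[`, "heavy"))
}

new_coarse_model <- function(label, kind, chain, resno, resid, xyz, b, heavy) {
  stopifnot(nrow(xyz) == length(label), all(is.finite(xyz)))
  dimnames(xyz) <- NULL
  structure(list(label = label, kind = kind, chain = chain,
                 resno = resno, resid = resid, xyz = xyz, b = b,
                 heavy = heavy, N = length(label)),
            class = "coarse_model")
}

#' @export
print.coarse_model <- function(x, ...) {
  cat(sprintf("coarse_model: %d nodes (%d residue, %d ligand), %d chain(s)\n",
              x$N, sum(x$kind == "residue"), sum(x$kind == "ligand"),
              length(unique(x$chain))))
  invisible(x)
}

#' Read a residue-to-residue alignment map
#'
#' Reads a whitespace-separated two-column pair list, as exported from an
#' external structural aligner. Lines starting with \code{#} are comments.
#' On disk the indices are 0-based (the external convention); in memory they
#' are converted to 1-based node indices.
#'
#' @param file Path to the pair list, or a character vector of its lines.
#' @param n_a,n_b Optional node counts of models A and B for range checking.
#' @return An \code{alignment_map}: integer matrix with columns \code{a},
#'   \code{b} (1-based node indices).
#' @export
read_alignment_map <- function(file, n_a = NULL, n_b = NULL) {
  lines <- if (length(file) == 1 && !grepl("\n", file, fixed = TRUE) &&
               file.exists(file)) readLines(file) else
    unlist(strsplit(file, "\n", fixed = TRUE))
  lines <- trimws(lines)
  lines <- lines[nzchar(lines) & !startsWith(lines, "#")]
  if (length(lines) == 0) stopf("alignment map is empty")
  fields <- strsplit(lines, "[[:space:]]+")
  if (any(lengths(fields) != 2)) stopf("alignment map rows must have 2 columns")
  vals <- suppressWarnings(vapply(fields, as.integer, integer(2)))
  if (any(is.na(vals))) stopf("non-integer entry in alignment map")
  alignment_map(vals[1, ] + 1L, vals[2, ] + 1L, n_a = n_a, n_b = n_b)
}

#' Construct an alignment map from index vectors
#'
#' @param a,b Equal-length vectors of 1-based node indices in models A and B.
#' @param n_a,n_b Optional node counts for range validation.
#' @return An \code{alignment_map} object.
#' @export
alignment_map <- function(a, b, n_a = NULL, n_b = NULL) {
  a <- as.integer(a); b <- as.integer(b)
  if (length(a) != length(b)) stopf("index vectors differ in length")
  if (any(a < 1) || any(b < 1)) stopf("alignment index out of range")
  if (!is.null(n_a) && any(a > n_a)) stopf("alignment index out of range for model A")
  if (!is.null(n_b) && any(b > n_b)) stopf("alignment index out of range for model B")
  if (anyDuplicated(a) || anyDuplicated(b)) stopf("mapping not one-to-one")
  structure(cbind(a = a, b = b), class = "alignment_map")
}

#' Write coarse-model coordinates as a C-alpha PDB file
#'
#' Residue nodes are written as ATOM CA records and ligand nodes as HETATM
#' records (one pseudo-atom per node). Missing B-factors are written as 0.00.
#' The file round-trips through \code{\link{read_structure}} and
#' \code{\link{build_coarse_model}} with coordinates equal to 0.001 Angstrom
#' (PDB precision).
#'
#' @param model A \code{coarse_model}.
#' @param file Output path.
#' @param coords Optional replacement coordinates: a 3N vector or an N x 3
#'   matrix (default: the model's own).
#' @return The path, invisibly.
#' @export
write_coarse_pdb <- function(model, file, coords = NULL) {
  stopifnot(inherits(model, "coarse_model"))
  xyz <- model$xyz
  if (!is.null(coords)) {
    if (is.matrix(coords)) coords <- as_flat(coords)
    if (length(coords) != 3 * model$N) {
      stopf("coordinate length %d does not match 3N = %d",
            length(coords), 3 * model$N)
    }
    xyz <- as_xyz(coords)
  }
  b <- ifelse(is.na(model$b), 0, model$b)
  is_lig <- model$kind == "ligand"
  bio3d::write.pdb(
    file = file,
    xyz = as_flat(xyz),
    type = ifelse(is_lig, "HETATM", "ATOM"),
    resno = model$resno,
    resid = model$resid,
    chain = model$chain,
    elety = ifelse(is_lig, "C1", "CA"),
    o = rep(1, model$N),
    b = b)
  invisible(file)
}
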