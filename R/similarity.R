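#' Per-amino-acid weight matrix of a hidden-unit group
#'
#' Reshapes a group's `N_v`-vector of weights into a `20 x Gamma` matrix:
#' entry `(k, gamma)` is the weight on visible unit `20*(gamma-1) + k`,
#' i.e. row `k` collects the `Gamma` position weights of one amino acid.
#'
#' @param model An `average_rbm` (or any model accepted by the interpret
#'   functions); a bare numeric vector is reshaped directly.
#' @param group_id Hidden-unit/group index (column of the weight matrix).
#' @returns A `20 x Gamma` matrix with rows named by [aa_alphabet].
#' @export
amino_acid_weight_matrix <- function(model, group_id = 1L) {
  w <- if (is.numeric(model) && is.null(dim(model))) model else {
    params <- as_params(model)
    if (group_id < 1 || group_id > params$n_hidden) {
      stop("unknown group ", group_id, call. = FALSE)
    }
    params$w[, group_id]
  }
  if (length(w) %% 20 != 0) stop("weight vector length not divisible by 20",
                                 call. = FALSE)
  m <- matrix(w, nrow = 20L)
  rownames(m) <- aa_alphabet
  colnames(m) <- seq_len(ncol(m))
  m
}

#' PCA of a group's per-amino-acid weights
#'
#' The 20 amino acids are the observations and the `Gamma` positions the
#' variables; the column-centred covariance is eigen-decomposed and the
#' top two scores returned.  Explained-variance fractions cover all
#' `Gamma` components and sum to 1.  When the individual member-unit
#' matrices of the group are supplied, the reported `explained` is the
#' mean of the per-member explained fractions (the group-matrix fractions
#' are kept as `explained_group`).
#'
#' @param m A `20 x Gamma` matrix from [amino_acid_weight_matrix()].
#' @param member_matrices Optional list of `20 x Gamma` matrices, one per
#'   group member unit.
#' @param group_id Identifier carried through to the result.
#' @returns An object of class `group_pca`: list with `coords` (tibble
#'   `residue`, `pc1`, `pc2`), `explained`, `explained_group`, `group_id`,
#'   `orientation` (`+1` until [orient_and_correlate()] is applied).
#' @export
group_pca <- function(m, member_matrices = NULL, group_id = 1L) {
  if (ncol(m) < 2) stop("need Gamma >= 2 positions for PCA", call. = FALSE)
  if (all(abs(sweep(m, 2, colMeans(m))) < 1e-12)) {
    stop("degenerate weight matrix: all amino-acid rows equal", call. = FALSE)
  }
  pc <- stats::prcomp(m, center = TRUE, scale. = FALSE)
  expl_one <- function(p) p$sdev^2 / sum(p$sdev^2)
  explained_group <- expl_one(pc)
  explained <- if (is.null(member_matrices)) explained_group else {
    rowMeans(vapply(member_matrices,
                    function(mm) expl_one(stats::prcomp(mm, center = TRUE)),
                    numeric(length(explained_group))))
  }
  scores <- pc$x
  structure(list(
    coords = tibble::tibble(residue = rownames(m),
                            pc1 = unname(scores[, 1]),
                            pc2 = unname(scores[, min(2, ncol(scores))])),
    explained = unname(explained),
    explained_group = unname(explained_group),
    group_id = group_id,
    orientation = 1),
    class = "group_pca")
}

#' @export
print.group_pca <- function(x, ...) {
  cat("<group_pca> group", x$group_id, "- explained:",
      paste(signif(100 * x$explained[1:2], 3), collapse = "% / "), "%\n")
  invisible(x)
}

#' The shipped hydrophobicity scale
#'
#' Reads a two-column TSV (`residue`, `value`) covering the 20 canonical
#' amino acids.  The default is the Fauchere-Pliska (1983) octanol/water
#' side-chain partition scale (unitless pi values, larger = more
#' hydrophobic), on which Trp is the most hydrophobic residue and Arg and
#' Lys the least.  Any user scale in the same format can be substituted.
#'
#' @param path Path to a scale TSV; default is the file shipped with the
#'   package.
#' @returns Tibble with columns `residue` and `value`, ordered as
#'   [aa_alphabet]; attribute `name` is the file's base name.
#' @export
read_hydro_scale <- function(path = NULL) {
  if (is.null(path)) {
    path <- system.file("extdata", "fauchere_pliska_1983.tsv",
                        package = "rbmotif", mustWork = TRUE)
  }
  tbl <- readr::read_tsv(path, col_types = "cd")
  names(tbl) <- c("residue", "value")
  if (!setequal(tbl$residue, aa_alphabet)) {
    stop("scale must cover exactly the 20 canonical residues", call. = FALSE)
  }
  tbl <- tbl[match(aa_alphabet, tbl$residue), ]
  attr(tbl, "name") <- sub("\\.[^.]*$", "", basename(path))
  tbl
}

#' Orient PC1 along a hydrophobicity scale and correlate
#'
#' Chooses the sign of PC1 so that its Pearson correlation with the scale
#' is non-negative (the applied sign is recorded as `orientation`; the raw
#' correlation is kept, so no information is lost).
#'
#' @param pca A `group_pca`.
#' @param scale A scale tibble from [read_hydro_scale()].
#' @returns List with `pca` (oriented) and `r` (the Pearson correlation
#'   after orientation); the pca gains fields `r`, `raw_r`.
#' @export
orient_and_correlate <- function(pca, scale = read_hydro_scale()) {
  stopifnot(inherits(pca, "group_pca"))
  vals <- scale$value[match(pca$coords$residue, scale$residue)]
  if (anyNA(vals)) stop("scale does not cover all residues", call. = FALSE)
  if (stats::sd(pca$coords$pc1) == 0) {
    stop("PC1 is constant; correlation undefined", call. = FALSE)
  }
  raw_r <- stats::cor(pca$coords$pc1, vals)
  s <- if (raw_r < 0) -1 else 1
  pca$coords$pc1 <- s * pca$coords$pc1
  pca$orientation <- s * pca$orientation
  pca$raw_r <- raw_r
  pca$r <- abs(raw_r)
  list(pca = pca, r = pca$r)
}

#' Weight PCA summary for every group of an aRBM
#'
#' Convenience wrapper: runs [group_pca()] + [orient_and_correlate()] for
#' each hidden unit of a consensus model.
#'
#' @param arbm An `average_rbm` (or other model).
#' @param scale Hydrophobicity scale tibble.
#' @param clustering Optional `unit_clustering`; when given, per-member
#'   weight matrices feed the averaged explained variances.
#' @returns Tibble with one row per group: `group`, `r`, `orientation`,
#'   `explained_pc1`, `explained_pc2` and a list-column `pca`.
#' @export
arbm_weight_pca <- function(arbm, scale = read_hydro_scale(), clustering = NULL) {
  params <- as_params(arbm)
  purrr::map_dfr(seq_len(params$n_hidden), function(g) {
    members <- NULL
    if (!is.null(clustering)) {
      idx <- which(clustering$units$group == g)
      members <- lapply(idx, function(i) {
        amino_acid_weight_matrix(clustering$units$weights[[i]] *
                                   clustering$units$sign[i])
      })
      if (length(members) == 0) members <- NULL
    }
    pc <- group_pca(amino_acid_weight_matrix(params$w[, g]),
                    member_matrices = members, group_id = g)
    oc <- orient_and_correlate(pc, scale)
    tibble::tibble(group = g, r = oc$r, orientation = oc$pca$orientation,
                   explained_pc1 = oc$pca$explained[1],
                   explained_pc2 = oc$pca$explained[2],
                   pca = list(oc$pca))
  })
}
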