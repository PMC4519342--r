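#' Backbone structure objects
#'
#' A `backbone` object holds the backbone heavy atoms (N, CA, CB, C, O) of a
#' single peptide conformation, one row of 3D coordinates (nm) per atom per
#' residue. It is the input to the secondary-structure collective variables.
#' Glycine-style residues may lack CB; fragment extraction substitutes CA.
#'
#' @param coords Named list of `n_res x 3` matrices for N, CA, CB, C, O
#'   (CB rows may be NA).
#' @param resid Integer residue ids (contiguous, 1-based by convention).
#' @return A `backbone` object.
#' @export
new_backbone <- function(coords, resid = seq_len(nrow(coords$N))) {
  for (at in c("N", "CA", "C", "O")) {
    if (is.null(coords[[at]]) || anyNA(coords[[at]])) {
      abort(paste0("backbone requires finite coordinates for atom ", at))
    }
  }
  if (is.null(coords$CB)) coords$CB <- matrix(NA_real_, nrow(coords$N), 3)
  n_res <- nrow(coords$N)
  stopifnot(all(vapply(coords, nrow, 0L) == n_res), length(resid) == n_res)
  if (n_res > 1 && any(diff(resid) != 1L)) {
    abort("backbone residues must be contiguous and ordered")
  }
  finite <- vapply(coords[c("N", "CA", "C", "O")],
                   function(m) all(is.finite(m)), TRUE)
  if (!all(finite)) abort("backbone coordinates must be finite")
  structure(list(coords = coords[BACKBONE_ATOMS],
                 resid = as.integer(resid), n_res = n_res),
            class = "backbone")
}

#' @export
print.backbone <- function(x, ...) {
  cat("<backbone> ", x$n_res, " residues, atoms N/CA/CB/C/O (nm)\n", sep = "")
  invisible(x)
}

#' @rdname new_backbone
#' @param x A `backbone` object.
#' @param ... Unused.
#' @method as_tibble backbone
#' @export
as_tibble.backbone <- function(x, ...) {
  purrr::map_dfr(BACKBONE_ATOMS, function(at) {
    m <- x$coords[[at]]
    tibble(resid = x$resid, atom = at,
           x = m[, 1], y = m[, 2], z = m[, 3])
  }) |>
    dplyr::arrange(.data$resid, match(.data$atom, BACKBONE_ATOMS)) |>
    dplyr::filter(is.finite(.data$x))
}

## Apply a rigid motion (rotation matrix R then translation t) to a backbone.
transform_backbone <- function(bb, R = diag(3), t = c(0, 0, 0)) {
  coords <- lapply(bb$coords, function(m) {
    out <- m %*% t(R)
    sweep(out, 2, -t)
  })
  new_backbone_keep_na(coords, bb$resid)
}

## internal constructor that tolerates NA CB rows already validated upstream
new_backbone_keep_na <- function(coords, resid) {
  structure(list(coords = coords[BACKBONE_ATOMS],
                 resid = as.integer(resid), n_res = nrow(coords$N)),
            class = "backbone")
}

#' Build an idealised peptide backbone
#'
#' Constructs a backbone from canonical bond geometry and kind-specific
#' dihedrals: `alpha_helix` (phi = -57, psi = -47), `beta_hairpin` (two
#' antiparallel strands at phi = -139, psi = 135 joined by a two-residue
#' type I' turn), `extended` (phi = -180, psi = 180) and `random_coil`
#' (phi/psi drawn uniformly from the helix and beta Ramachandran boxes,
#' reproducibly from `seed`).
#'
#' @param kind One of `"alpha_helix"`, `"beta_hairpin"`, `"extended"`,
#'   `"random_coil"`.
#' @param n_res Number of residues (>= 6; >= 8 for hairpins).
#' @param seed Integer seed, used only for `random_coil`.
#' @return A [new_backbone()] object.
#' @examples
#' helix <- build_ideal_structure("alpha_helix", 12)
#' @export
build_ideal_structure <- function(kind = c("alpha_helix", "beta_hairpin",
                                           "extended", "random_coil"),
                                  n_res, seed = 1L) {
  kind <- match.arg(kind)
  if (n_res < 6) abort("need at least 6 residues")
  if (kind == "beta_hairpin" && n_res < 8) {
    abort("a beta hairpin needs at least 8 residues")
  }
  dh <- switch(kind,
    alpha_helix = {
      d <- IDEAL_DIHEDRALS$alpha_helix
      list(phi = rep(d["phi"], n_res), psi = rep(d["psi"], n_res))
    },
    extended = {
      d <- IDEAL_DIHEDRALS$extended
      list(phi = rep(d["phi"], n_res), psi = rep(d["psi"], n_res))
    },
    beta_hairpin = hairpin_dihedrals(n_res),
    random_coil = {
      old <- get_rng_state()
      on.exit(set_rng_state(old), add = TRUE)
      set.seed(seed)
      boxes <- RAMA_BOXES
      ## phi and psi drawn independently from the allowed boxes, so no
      ## residue is forced into a coherent helix/beta conformation
      pick_phi <- sample(c("helix", "beta"), n_res, replace = TRUE)
      pick_psi <- sample(c("helix", "beta"), n_res, replace = TRUE)
      phi <- vapply(pick_phi, function(b) runif(1, boxes[[b]]$phi[1], boxes[[b]]$phi[2]), 0)
      psi <- vapply(pick_psi, function(b) runif(1, boxes[[b]]$psi[1], boxes[[b]]$psi[2]), 0)
      list(phi = phi, psi = psi)
    })
  new_backbone(build_backbone_coords(dh$phi, dh$psi))
}

## Hairpin dihedral schedule: strands flank a central two-residue type I'
## turn; for odd n the extra residue extends the first strand.
hairpin_dihedrals <- function(n_res) {
  beta <- IDEAL_DIHEDRALS$antiparallel_beta
  t1 <- IDEAL_DIHEDRALS$turn1
  t2 <- IDEAL_DIHEDRALS$turn2
  n_strand2 <- (n_res - 2L) %/% 2L
  n_strand1 <- n_res - 2L - n_strand2
  phi <- c(rep(beta["phi"], n_strand1), t1["phi"], t2["phi"],
           rep(beta["phi"], n_strand2))
  psi <- c(rep(beta["psi"], n_strand1), t1["psi"], t2["psi"],
           rep(beta["psi"], n_strand2))
  list(phi = unname(phi), psi = unname(psi))
}

get_rng_state <- function() {
  if (exists(".Random.seed", envir = globalenv(), inherits = FALSE)) {
    get(".Random.seed", envir = globalenv())
  } else {
    NULL
  }
}
set_rng_state <- function(state) {
  if (is.null(state)) {
    if (exists(".Random.seed", envir = globalenv(), inherits = FALSE)) {
      rm(".Random.seed", envir = globalenv())
    }
  } else {
    assign(".Random.seed", state, envir = globalenv())
  }
  invisible(NULL)
}

#' Read and write backbone PDB files
#'
#' Thin wrappers around bio3d's PDB parser restricted to the backbone atom
#' set. Coordinates are converted between the PDB angstrom convention and
#' the package-internal nm.
#'
#' @param path Path to a PDB file.
#' @return `read_backbone_pdb()`: a [new_backbone()] object;
#'   `read_backbone_pdb_frames()`: a list of them (one per MODEL).
#' @export
read_backbone_pdb <- function(path) {
  frames <- read_backbone_pdb_frames(path)
  if (length(frames) == 0) abort(paste0("no backbone atoms found in ", path))
  frames[[1]]
}

#' @rdname read_backbone_pdb
#' @export
read_backbone_pdb_frames <- function(path) {
  pdb <- bio3d::read.pdb(path, multi = TRUE, verbose = FALSE)
  sel <- pdb$atom$elety %in% BACKBONE_ATOMS & pdb$atom$type == "ATOM"
  if (!any(sel)) abort(paste0("no backbone atoms found in ", path))
  atom <- pdb$atom[sel, ]
  xyz <- pdb$xyz
  n_models <- nrow(xyz)
  idx <- which(sel)
  lapply(seq_len(n_models), function(mi) {
    resids <- sort(unique(atom$resno))
    coords <- lapply(setNames(BACKBONE_ATOMS, BACKBONE_ATOMS), function(at) {
      m <- matrix(NA_real_, length(resids), 3)
      rows <- which(atom$elety == at)
      for (r in rows) {
        ai <- idx[r]
        m[match(atom$resno[r], resids), ] <-
          xyz[mi, (3 * ai - 2):(3 * ai)] / 10  # angstrom -> nm
      }
      m
    })
    new_backbone(coords, resid = resids - min(resids) + 1L)
  })
}

#' @rdname read_backbone_pdb
#' @param bb A `backbone` object, or list of them for a multi-MODEL file.
#' @export
write_backbone_pdb <- function(bb, path) {
  frames <- if (inherits(bb, "backbone")) list(bb) else bb
  con <- file(path, "w")
  on.exit(close(con))
  for (mi in seq_along(frames)) {
    fr <- frames[[mi]]
    if (length(frames) > 1) writeLines(sprintf("MODEL     %4d", mi), con)
    serial <- 0L
    for (i in seq_len(fr$n_res)) {
      resname <- if (anyNA(fr$coords$CB[i, ])) "GLY" else "ALA"
      for (at in BACKBONE_ATOMS) {
        xyz <- fr$coords[[at]][i, ] * 10  # nm -> angstrom
        if (anyNA(xyz)) next
        serial <- serial + 1L
        writeLines(sprintf(
          "ATOM  %5d  %-3s %3s A%4d    %8.3f%8.3f%8.3f  1.00  0.00",
          serial, at, resname, fr$resid[i], xyz[1], xyz[2], xyz[3]), con)
      }
    }
    if (length(frames) > 1) writeLines("ENDMDL", con)
  }
  writeLines("END", con)
  invisible(path)
}
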