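# Native-contact machinery: atom-pair contact maps, the fraction of native
# contacts Q, per-residue Phi-values from ensembles or mutational ddG
# tables, the Phi-restraint pseudo-energy, and Bronsted statistics.

.BACKBONE_NAMES <- c("N", "CA", "C", "O", "OXT", "H", "H1", "H2", "H3",
                     "HA", "HN")

# indices of protein side-chain heavy atoms (C-beta and beyond; glycine
# contributes none)
.side_chain_heavy <- function(top) {
  a <- top$atoms
  which(a$segment == "protein" & a$is_heavy &
          !(a$name %in% .BACKBONE_NAMES))
}

#' Native-contact map from a native structure
#'
#' Native contacts between two residues that are not sequence neighbours
#' are the pairs of heavy side-chain atoms within `cutoff` in the native
#' structure.  Glycine has no side-chain heavy atom and therefore carries no
#' contacts; alanine contributes its C-beta.
#'
#' @param native List with `topology` and `frame` (the native structure).
#' @param cutoff Native-contact distance cutoff in nm (default 0.65).
#' @param neighbour_exclusion Minimum residue separation `|i - j|`
#'   (default 2: only sequence neighbours are excluded).
#' @return Object of class `"native_contact_map"`: `atom_pairs` (two-column
#'   atom-index matrix), `residue_pairs` (data frame `res_i`, `res_j`,
#'   `n_pairs`), `native_dist` (per atom pair, nm), `cutoff` and
#'   `neighbour_exclusion`.
#' @export
native_contacts <- function(native, cutoff = 0.65, neighbour_exclusion = 2) {
  top <- native$topology
  fr <- native$frame
  sc <- .side_chain_heavy(top)
  resid <- top$atoms$resid
  out_i <- integer(0); out_j <- integer(0)
  if (length(sc) >= 2) {
    cand <- utils::combn(sc, 2)
    keep <- abs(resid[cand[1, ]] - resid[cand[2, ]]) >= neighbour_exclusion
    cand <- cand[, keep, drop = FALSE]
    if (ncol(cand)) {
      d <- min_image_distance(fr, cand[1, ], cand[2, ])
      sel <- d <= cutoff
      out_i <- cand[1, sel]; out_j <- cand[2, sel]
      nd <- d[sel]
    }
  }
  atom_pairs <- cbind(i = out_i, j = out_j)
  if (length(out_i)) {
    rp <- data.frame(res_i = pmin(resid[out_i], resid[out_j]),
                     res_j = pmax(resid[out_i], resid[out_j]))
    agg <- stats::aggregate(list(n_pairs = rep(1L, nrow(rp))),
                            by = rp, FUN = sum)
  } else {
    nd <- numeric(0)
    agg <- data.frame(res_i = integer(0), res_j = integer(0),
                      n_pairs = integer(0))
  }
  structure(list(atom_pairs = atom_pairs, residue_pairs = agg,
                 native_dist = if (length(out_i)) nd else numeric(0),
                 cutoff = cutoff, neighbour_exclusion = neighbour_exclusion,
                 resid_of_atom = resid),
            class = "native_contact_map")
}

#' @export
print.native_contact_map <- function(x, ...) {
  cat(sprintf(
    "native contact map: %d atom pairs over %d residue pairs (cutoff %.2f nm)\n",
    nrow(x$atom_pairs), nrow(x$residue_pairs), x$cutoff))
  invisible(x)
}

.formed_flags <- function(fr, map, formation_cutoff) {
  d <- min_image_distance(fr, map$atom_pairs[, 1], map$atom_pairs[, 2])
  d <= formation_cutoff
}

#' Fraction of native contacts Q
#'
#' Q is the share of native atom-pair contacts currently formed, i.e.
#' within `formation_cutoff` in the query frame.
#'
#' @param fr A [frame()].
#' @param map A [native_contacts()] map.
#' @param formation_cutoff Formation cutoff in nm; defaults to the map's
#'   native cutoff (no tolerance inflation).
#' @return Q in `[0, 1]`.
#' @export
fraction_native_contacts <- function(fr, map, formation_cutoff = NULL) {
  if (!nrow(map$atom_pairs)) stop("empty native contact map")
  if (is.null(formation_cutoff)) formation_cutoff <- map$cutoff
  mean(.formed_flags(fr, map, formation_cutoff))
}

#' Residue-residue contact-formation map
#'
#' Entry (i, j) is the weight-averaged fraction of the native atom-pair
#' contacts between residues i and j that are formed; symmetric, `NA`
#' where no native contact exists.
#'
#' @param ens An [ensemble()].
#' @inheritParams fraction_native_contacts
#' @return A residue x residue numeric matrix.
#' @export
contact_formation_map <- function(ens, map, formation_cutoff = NULL) {
  if (!nrow(map$atom_pairs)) stop("empty native contact map")
  if (is.null(formation_cutoff)) formation_cutoff <- map$cutoff
  freq <- numeric(nrow(map$atom_pairs))
  for (k in seq_len(n_frames(ens))) {
    freq <- freq + ens$weights[k] *
      .formed_flags(ens$frames[[k]], map, formation_cutoff)
  }
  resid <- map$resid_of_atom
  ri <- resid[map$atom_pairs[, 1]]; rj <- resid[map$atom_pairs[, 2]]
  nres <- max(ens$topology$atoms$resid)
  m <- matrix(NA_real_, nres, nres)
  for (p in seq_len(nrow(map$residue_pairs))) {
    i <- map$residue_pairs$res_i[p]; j <- map$residue_pairs$res_j[p]
    sel <- (pmin(ri, rj) == i) & (pmax(ri, rj) == j)
    m[i, j] <- m[j, i] <- mean(freq[sel])
  }
  m
}

#' Per-residue Phi-value set
#'
#' @param residue Integer residue ids.
#' @param phi Phi-values (may contain `NA` for invalid residues).
#' @param valid Logical validity flags.
#' @return Object of class `"phi_set"` (a data frame).
#' @export
phi_set <- function(residue, phi, valid = !is.na(phi)) {
  if (any(valid & (is.na(phi) | phi < 0 - 1e-12 | phi > 1 + 1e-12))) {
    stop("valid Phi-values must lie in [0, 1]")
  }
  structure(data.frame(residue = as.integer(residue), phi = phi,
                       valid = valid),
            class = c("phi_set", "data.frame"))
}

#' Per-residue Phi-values from a conformational ensemble
#'
#' The Phi-value of residue i is the weight-averaged fraction of the native
#' atom-pair contacts involving i that are formed.  Residues without native
#' contacts are flagged invalid.
#'
#' @inheritParams contact_formation_map
#' @return A [phi_set()].
#' @export
phi_from_ensemble <- function(ens, map, formation_cutoff = NULL) {
  if (!nrow(map$atom_pairs)) stop("empty native contact map")
  if (is.null(formation_cutoff)) formation_cutoff <- map$cutoff
  resid <- map$resid_of_atom
  ri <- resid[map$atom_pairs[, 1]]; rj <- resid[map$atom_pairs[, 2]]
  nres <- max(ens$topology$atoms$resid)
  total <- numeric(nres)
  for (r in seq_len(nres)) total[r] <- sum(ri == r) + sum(rj == r)
  formed_w <- numeric(nres)
  for (k in seq_len(n_frames(ens))) {
    f <- .formed_flags(ens$frames[[k]], map, formation_cutoff)
    cnt <- numeric(nres)
    t1 <- tapply(f, ri, sum); t2 <- tapply(f, rj, sum)
    cnt[as.integer(names(t1))] <- cnt[as.integer(names(t1))] + t1
    cnt[as.integer(names(t2))] <- cnt[as.integer(names(t2))] + t2
    formed_w <- formed_w + ens$weights[k] * cnt
  }
  phi <- ifelse(total > 0, formed_w / total, NA_real_)
  phi_set(seq_len(nres), phi, valid = total > 0)
}

#' Phi-restraint pseudo-energy
#'
#' `E = k * sum((phi_sim - phi_exp)^2)` over residues valid in both sets;
#' experimental values outside `[0, 1]` are excluded (only Phi-values
#' between 0 and 1 are meaningful as structural restraints).
#'
#' @param phi_sim,phi_exp [phi_set()] objects over matching residue ids.
#' @param k Restraint constant (kJ/mol).
#' @return Energy in kJ/mol.
#' @export
phi_restraint_energy <- function(phi_sim, phi_exp, k = 1) {
  m <- merge(as.data.frame(phi_sim), as.data.frame(phi_exp),
             by = "residue", suffixes = c("_sim", "_exp"))
  use <- m$valid_sim & m$valid_exp & !is.na(m$phi_exp) &
    m$phi_exp >= 0 & m$phi_exp <= 1
  if (!any(use)) stop("no residue is valid in both Phi sets")
  k * sum((m$phi_sim[use] - m$phi_exp[use])^2)
}

#' Phi-values from mutational ddG data
#'
#' `Phi = (ddG_DN - ddG_TSN) / ddG_DN` per mutant (destabilisation
#' energies, mutant minus wild type).  Mutants with `|ddG_DN| < min_ddg`
#' (unreliable Phi) and residues whose Phi falls outside `[0, 1]` (not
#' interpretable as a contact fraction) are flagged invalid; multiple
#' mutants at one residue are averaged with a warning.
#'
#' @param table A `ddg_table` (columns `residue`, `ddG_DN`, `ddG_TSN`).
#' @param min_ddg Reliability floor in kJ/mol (default 2.5, about
#'   0.6 kcal/mol).
#' @return A [phi_set()].
#' @export
phi_from_ddg <- function(table, min_ddg = 2.5) {
  if (!nrow(table)) stop("empty ddG table")
  if (anyDuplicated(table$residue)) {
    warning("multiple mutants at one residue; averaging their Phi-values")
  }
  phi_mut <- (table$ddG_DN - table$ddG_TSN) / table$ddG_DN
  ok_mut <- abs(table$ddG_DN) >= min_ddg
  res <- sort(unique(table$residue))
  phi <- vapply(res, function(r) {
    sel <- table$residue == r & ok_mut
    if (!any(sel)) NA_real_ else mean(phi_mut[sel])
  }, numeric(1))
  # only Phi-values inside [0, 1] are structurally meaningful restraints
  phi_set(res, phi, valid = !is.na(phi) & phi >= 0 & phi <= 1)
}

#' Bronsted statistics of a ddG table
#'
#' Pearson correlation and least-squares line of the activation
#' destabilisation `ddG_TSN` against the equilibrium destabilisation
#' `ddG_DN` across mutants.  A linear Bronsted plot is the signature of a
#' nucleation-condensation folding mechanism; a scattered one of
#' diffusion-collision.
#'
#' @param table A `ddg_table`.
#' @return Object of class `"bronsted_result"`: `pearson_r`, `slope`,
#'   `intercept`, `n`.
#' @export
bronsted <- function(table) {
  n <- nrow(table)
  if (n < 3) stop("Bronsted analysis needs at least 3 mutants")
  if (sd(table$ddG_DN) == 0 || sd(table$ddG_TSN) == 0) {
    stop("zero variance in a ddG column")
  }
  fit <- lm(ddG_TSN ~ ddG_DN, data = table)
  structure(list(pearson_r = cor(table$ddG_DN, table$ddG_TSN),
                 slope = unname(coef(fit)[2]),
                 intercept = unname(coef(fit)[1]), n = n),
            class = "bronsted_result")
}

#' @export
print.bronsted_result <- function(x, ...) {
  cat(sprintf("Bronsted plot: r = %.3f, slope = %.3f, n = %d\n",
              x$pearson_r, x$slope, x$n))
  invisible(x)
}

#' Read / write ddG tables and Phi sets (TSV)
#'
#' ddG tables use the header `residue ddG_DN ddG_TSN` (kJ/mol); Phi sets
#' use `residue phi valid`.
#'
#' @param path File path.
#' @return `read_ddg_table` a `ddg_table`; `read_phi_set` a [phi_set()].
#' @export
read_ddg_table <- function(path) {
  d <- read.table(path, header = TRUE, sep = "\t",
                  stringsAsFactors = FALSE)
  need <- c("residue", "ddG_DN", "ddG_TSN")
  if (!all(need %in% names(d))) {
    stop("ddG table must have columns: ", paste(need, collapse = ", "))
  }
  if (any(!is.finite(d$ddG_DN)) || any(!is.finite(d$ddG_TSN))) {
    stop("ddG table contains non-finite values")
  }
  structure(d[, need], class = c("ddg_table", "data.frame"))
}

#' @rdname read_ddg_table
#' @param table A `ddg_table`.
#' @export
write_ddg_table <- function(table, path) {
  write.table(table, path, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}

#' @rdname read_ddg_table
#' @export
read_phi_set <- function(path) {
  d <- read.table(path, header = TRUE, sep = "\t",
                  stringsAsFactors = FALSE)
  phi_set(d$residue, d$phi, as.logical(d$valid))
}

#' @rdname read_ddg_table
#' @param phi A [phi_set()].
#' @export
write_phi_set <- function(phi, path) {
  write.table(as.data.frame(phi), path, sep = "\t", quote = FALSE,
              row.names = FALSE)
  invisible(path)
}
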