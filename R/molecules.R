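# Molecule templates: the linear collagen-like molecule and its pre-tangled
# variants.
#
# Bead types: 1 = HEAD (attractive patch, one merged 7S/NC1-like chemistry),
# 2 = BODY (excluded volume only), 3 = TANGLE (a crosslink site; non-bonded
# behaviour identical to BODY, but treated as a fixed degree-3 node during
# network extraction).

BEAD_HEAD <- 1L
BEAD_BODY <- 2L
BEAD_TANGLE <- 3L

new_template <- function(id, types, xy, bonds, angles) {
  structure(list(id = id, types = as.integer(types), xy = xy,
                 bonds = bonds, angles = angles),
            class = "cw_template")
}

#' @export
print.cw_template <- function(x, ...) {
  cat(sprintf("<cw_template> %s: %d beads (%d head, %d tangle), %d bonds, %d angles\n",
              x$id, length(x$types), sum(x$types == BEAD_HEAD),
              sum(x$types == BEAD_TANGLE), nrow(x$bonds),
              if (is.null(x$angles)) 0L else nrow(x$angles)))
  invisible(x)
}

#' Molecule templates
#'
#' `molecule_template()` returns the rest geometry and bonded topology of one
#' molecule type:
#'
#' * `linear` - the standard molecule: two head beads joined by a straight
#'   chain of body beads at the per-bond rest length (five 60 nm bonds by
#'   default), end-to-end rest length `l_eqm`.
#' * `tangle_b` - one tangling site: a three-arm star whose central TANGLE
#'   bead is a permanent crosslink. Each arm ends in a head bead at an arc
#'   (along-bond) distance `arc` = 150 nm from the tangle site, i.e. one full
#'   strand passing straight through the crosslink plus one half-strand arm.
#' * `tangle_c` - two tangling sites joined by a 150 nm bridge, each carrying
#'   two head arms (four heads in total).
#'
#' Angle potentials act along each strand (straight rest geometry); the
#' tangle site itself is a free pivot between strands.
#'
#' @param id one of "linear", "tangle_b", "tangle_c"
#' @param params [potential_params()]
#' @param arc head-to-tangle arc distance (nm); must be a whole multiple of
#'   the per-bond rest length
#' @return a `cw_template`
#' @export
molecule_template <- function(id = c("linear", "tangle_b", "tangle_c"),
                              params = potential_params(), arc = 150) {
  id <- match.arg(id)
  r <- params$bond_rest
  if (id == "linear") {
    nb <- round(params$l_eqm / r)
    if (abs(nb * r - params$l_eqm) > 1e-9 * params$l_eqm || nb < 1)
      stop("linear template needs l_eqm to be a whole multiple of bond_rest ",
           "(end-to-end rest length must equal l_eqm)", call. = FALSE)
    n <- nb + 1
    xy <- cbind(seq(0, params$l_eqm, by = r) - params$l_eqm / 2, rep(0, n))
    types <- c(BEAD_HEAD, rep(BEAD_BODY, n - 2), BEAD_HEAD)
    angles <- if (n >= 3) cbind(i = 1:(n - 2), j = 2:(n - 1), k = 3:n) else
      NULL
    return(new_template("linear", types, xy,
                        bonds = cbind(i = 1:nb, j = 2:n, rest = r),
                        angles = angles))
  }
  if (!is.numeric(arc) || length(arc) != 1 || arc <= 0)
    stop("`arc` must be a positive head-to-tangle distance in nm",
         call. = FALSE)
  na <- 3L      # bonds per arm: 50-nm spacing keeps the first body bead
  r <- arc / na # close enough to the head that arm clumping is penalised
  # an arm is a straight chain of `na` bonds from the tangle bead to a head
  arm <- function(origin_idx, dir, start_idx) {
    xy <- t(sapply(seq_len(na), function(s) dir * s * r))
    types <- c(rep(BEAD_BODY, na - 1), BEAD_HEAD)
    ii <- c(origin_idx, start_idx + seq_len(na - 1) - 1)
    jj <- start_idx + seq_len(na) - 1
    list(xy = xy, types = types, bonds = cbind(i = ii, j = jj, rest = r))
  }
  build_star <- function(centres_xy, centre_types, arms_spec, bridges) {
    xy <- centres_xy; types <- centre_types
    bonds <- bridges
    angles_paths <- list()
    for (a in arms_spec) {
      start <- nrow(xy) + 1
      am <- arm(a$origin, a$dir, start)
      xy <- rbind(xy, sweep(am$xy, 2, centres_xy[a$origin, ], "+"))
      types <- c(types, am$types)
      bonds <- rbind(bonds, am$bonds)
      angles_paths[[length(angles_paths) + 1]] <-
        c(a$origin, start:(start + na - 1))
    }
    # angle triples along each strand path (arms are straight at rest;
    # the tangle site itself is a free pivot between strands)
    angles <- do.call(rbind, lapply(angles_paths, function(p) {
      if (length(p) < 3) return(NULL)
      cbind(i = p[1:(length(p) - 2)], j = p[2:(length(p) - 1)],
            k = p[3:length(p)])
    }))
    list(xy = xy, types = types, bonds = bonds, angles = angles)
  }
  if (id == "tangle_b") {
    # three 150-nm arms around one tangle site (one strand runs straight
    # through the crosslink, plus a half-strand arm)
    sp <- build_star(matrix(0, 1, 2), BEAD_TANGLE,
                     list(list(origin = 1, dir = c(1, 0)),
                          list(origin = 1, dir = c(-1, 0)),
                          list(origin = 1, dir = c(0, 1))),
                     bridges = cbind(i = integer(0), j = integer(0),
                                     rest = numeric(0)))
    return(new_template("tangle_b", sp$types, sp$xy, sp$bonds, sp$angles))
  }
  # tangle_c: two tangle sites joined by an `arc`-long bridge, each with two
  # head arms perpendicular to the bridge
  nbr <- na # bridge has the same length as an arm
  bridge_xy <- t(sapply(seq_len(nbr - 1), function(s) c(s * r, 0)))
  centres <- rbind(c(0, 0), c(arc, 0))
  ct <- c(BEAD_TANGLE, BEAD_TANGLE)
  if (nbr >= 2) {
    centres <- rbind(centres, bridge_xy)
    ct <- c(ct, rep(BEAD_BODY, nbr - 1))
  }
  bridge_chain <- c(1, if (nbr >= 2) 2 + seq_len(nbr - 1) else NULL, 2)
  bridges <- cbind(i = bridge_chain[-length(bridge_chain)],
                   j = bridge_chain[-1], rest = r)
  sp <- build_star(centres, ct,
                   list(list(origin = 1, dir = c(0, 1)),
                        list(origin = 1, dir = c(0, -1)),
                        list(origin = 2, dir = c(0, 1)),
                        list(origin = 2, dir = c(0, -1))),
                   bridges = bridges)
  # bridge is also a straight strand: constrain its internal angles
  extra <- if (length(bridge_chain) >= 3)
    cbind(i = bridge_chain[1:(length(bridge_chain) - 2)],
          j = bridge_chain[2:(length(bridge_chain) - 1)],
          k = bridge_chain[3:length(bridge_chain)]) else NULL
  angles <- rbind(sp$angles, extra)
  new_template("tangle_c", sp$types, sp$xy, sp$bonds, angles)
}

#' Pre-tangled molecule template set
#'
#' Convenience wrapper returning the tangled templates used when seeding a
#' simulation with lateral crosslinks, mirroring the substitution experiment
#' in which a fraction of linear molecules is replaced by tangled composites.
#'
#' @param f_b,f_c substitution fractions for the one- and two-site templates;
#'   only validated here (`f_b + f_c <= 1`), the substitution itself is done
#'   by [substitute_tangled()]
#' @param arc head-to-tangle arc distance (nm, default 150)
#' @param params [potential_params()]
#' @return list with elements `tangle_b`, `tangle_c` and the validated spec
#' @export
make_tangled_templates <- function(f_b = 0, f_c = 0, arc = 150,
                                   params = potential_params()) {
  if (f_b < 0 || f_c < 0 || f_b + f_c > 1)
    stop("substitution fractions must satisfy f_b, f_c >= 0 and f_b + f_c <= 1",
         call. = FALSE)
  list(tangle_b = molecule_template("tangle_b", params, arc),
       tangle_c = molecule_template("tangle_c", params, arc),
       spec = list(f_b = f_b, f_c = f_c, arc = arc))
}

# number of bonded branches at each bead of a template
template_branches <- function(tpl) {
  tabulate(c(tpl$bonds[, "i"], tpl$bonds[, "j"]), nbins = length(tpl$types))
}
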