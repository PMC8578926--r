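#' Read the packaged arterial-tree configuration
#'
#' The default reduced tree is shipped as an editable YAML file: twelve tapered
#' segments (aortic trunk down to an iliac terminal, plus brachiocephalic /
#' right-subclavian, left-carotid and left-subclavian / axillary / brachial
#' branches) with four three-element Windkessel terminals.
#'
#' @param path Path to a tree YAML file; default is the packaged one.
#' @return A list with `reference` constants and a `segments` tibble.
#' @export
read_tree_config <- function(path = NULL) {
  if (is.null(path)) {
    path <- system.file("extdata", "arterial_tree.yaml", package = "pulsees")
  }
  cfg <- yaml::read_yaml(path)
  seg <- purrr::map_dfr(cfg$segments, function(s) {
    term <- s$terminal
    tibble(
      id = s$id,
      parent = ifelse(is.null(s$parent), NA_character_, s$parent),
      length_cm = s$length_cm,
      d_in_cm = s$d_in_cm,
      d_out_cm = s$d_out_cm,
      stiffness_ratio = s$stiffness_ratio,
      n_elements = as.integer(s$n_elements),
      is_terminal = !is.null(term),
      R_p_ratio = if (is.null(term)) NA_real_ else term$R_p_ratio,
      R_c_fraction = if (is.null(term)) NA_real_ else term$R_c_fraction,
      C_t_ratio = if (is.null(term)) NA_real_ else term$C_t_ratio
    )
  })
  list(reference = cfg$reference, segments = seg)
}

#' Build the default arterial tree at given scales
#'
#' Starts from the packaged reference geometry (180 cm subject, 33.2 mm aortic
#' inlet, aortic distensibility 5.86e-3/mmHg) and applies uniform scalings:
#' all lengths by `height/180`, all diameters by `aortic_diameter_scale`,
#' per-segment distensibility is `distensibility * stiffness_ratio`, terminal
#' peripheral resistances keep their packaged ratios but are rescaled so that
#' the parallel total of `R_c + R_p` equals `TPR`, and terminal compliances
#' are multiplied by `Ct_scale`.
#'
#' @param height Subject height, cm.
#' @param aortic_diameter_scale Uniform diameter scale (1 = reference).
#' @param distensibility Aortic distensibility, `1e-3 / mmHg`.
#' @param TPR Total peripheral resistance, mmHg.s/ml.
#' @param Ct_scale Uniform terminal-compliance scale.
#' @param config Optional configuration from [read_tree_config()].
#' @return An object of class `arterial_tree`: a list with a `segments`
#'   tibble (geometry in cm, distensibility in 1e-3/mmHg) and a `terminals`
#'   tibble (`R_c`, `R_p` in mmHg.s/ml, `C_t` in ml/mmHg, `P_out` in mmHg).
#' @examples
#' tree <- build_default_tree()
#' tree$segments
#' @export
build_default_tree <- function(height = 180, aortic_diameter_scale = 1,
                               distensibility = 5.86, TPR = 1.28,
                               Ct_scale = 1, config = NULL) {
  if (height <= 0 || aortic_diameter_scale <= 0 || distensibility <= 0 ||
      TPR <= 0 || Ct_scale <= 0) {
    abort("all tree scale arguments must be positive")
  }
  if (is.null(config)) config <- .default_tree_config()
  ref <- config$reference
  seg <- config$segments
  seg$length_cm <- seg$length_cm * height / ref$height_cm
  seg$d_in_cm <- seg$d_in_cm * aortic_diameter_scale
  seg$d_out_cm <- seg$d_out_cm * aortic_diameter_scale
  seg$distensibility <- distensibility * seg$stiffness_ratio

  term <- seg[seg$is_terminal, c("id", "R_p_ratio", "R_c_fraction", "C_t_ratio")]
  # R_p_i = ratio_i * k, R_c_i = frac_i * R_p_i; choose k so that the
  # parallel combination of (R_c + R_p) over beds equals TPR exactly
  k <- TPR * sum(1 / ((1 + term$R_c_fraction) * term$R_p_ratio))
  term$R_p <- term$R_p_ratio * k
  term$R_c <- term$R_c_fraction * term$R_p
  term$C_t <- Ct_scale * ref$terminal_Ct_total * term$C_t_ratio /
    sum(term$C_t_ratio)
  term$P_out <- ref$venous_pressure_mmHg

  structure(
    list(segments = seg,
         terminals = term[, c("id", "R_c", "R_p", "C_t", "P_out")],
         TPR = TPR),
    class = "arterial_tree"
  )
}

# cache the packaged config (read once per session)
.tree_cache <- new.env(parent = emptyenv())
.default_tree_config <- function() {
  if (is.null(.tree_cache$cfg)) .tree_cache$cfg <- read_tree_config()
  .tree_cache$cfg
}

#' @export
print.arterial_tree <- function(x, ...) {
  cat("<arterial_tree> ", nrow(x$segments), " segments, ",
      nrow(x$terminals), " Windkessel terminals, TPR ",
      format(x$TPR, digits = 4), " mmHg.s/ml\n", sep = "")
  invisible(x)
}

# Assemble the lumped-ladder network (SI units) from an arterial tree.
# Each segment is split into n_elements Pi-elements: a branch with Poiseuille
# resistance R = 128 mu l / (pi d^4) and inertance L = 4 rho l / (pi d^2)
# using the local tapered diameter, plus compliance C = D A l split equally
# between the element's two end nodes.
.assemble_network <- function(tree, blood = blood_properties()) {
  seg <- tree$segments
  nseg <- nrow(seg)
  # node 0 = aortic root; allocate nodes in segment order
  u <- integer(0); v <- integer(0); R <- numeric(0); L <- numeric(0)
  Cnode <- numeric(1)  # starts with root node
  distal_node <- integer(nseg)     # distal node per segment (0-based)
  first_branch <- integer(nseg)    # first branch per segment (0-based)
  names(distal_node) <- names(first_branch) <- seg$id

  for (i in seq_len(nseg)) {
    inlet <- if (is.na(seg$parent[i])) 0L else distal_node[[seg$parent[i]]]
    nel <- seg$n_elements[i]
    l_el <- seg$length_cm[i] / nel / 100            # m
    D_si <- .dist_si(seg$distensibility[i])
    first_branch[i] <- length(u)
    up <- inlet
    for (j in seq_len(nel)) {
      frac <- (j - 0.5) / nel
      d <- (seg$d_in_cm[i] + frac * (seg$d_out_cm[i] - seg$d_in_cm[i])) / 100
      A <- pi * d^2 / 4
      Rb <- 128 * blood$mu * l_el / (pi * d^4)
      Lb <- 4 * blood$rho * l_el / (pi * d^2)
      Cel <- D_si * A * l_el
      new_node <- length(Cnode)                     # 0-based id
      Cnode <- c(Cnode, 0)
      u <- c(u, up); v <- c(v, new_node); R <- c(R, Rb); L <- c(L, Lb)
      Cnode[up + 1L] <- Cnode[up + 1L] + Cel / 2
      Cnode[new_node + 1L] <- Cnode[new_node + 1L] + Cel / 2
      up <- new_node
    }
    distal_node[i] <- up
  }

  term <- tree$terminals
  term_node <- distal_node[term$id]
  list(
    u = as.integer(u), v = as.integer(v), R = R, L = L, Cnode = Cnode,
    term_node = as.integer(term_node),
    term_Rc = .res_si(term$R_c), term_Rp = .res_si(term$R_p),
    term_Ct = .cap_si(term$C_t), P_out = term$P_out[1] * MMHG_PA,
    distal_node = distal_node, first_branch = first_branch
  )
}
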