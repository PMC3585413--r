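#' Lamellipodium protrusion and cell polarity
#'
#' Protrusion acts only at the leading edge: the contact-rim nodes (in contact
#' with the substrate but bordering non-contact neighbors) that project inside
#' the ligand pattern and, in migration mode, face the polarity direction.
#' Each leading node receives a constant 300 pN force along its outward
#' in-plane normal; any non-uniformity of the net force at a node arises
#' solely from vector addition with the other forces, never from scaling
#' the protrusion itself.
#'
#' @name protrusion
NULL

#' Cell polarity state
#'
#' @param direction in-plane unit 2- or 3-vector (z component forced to 0)
#' @return list of class `polarity`
#' @export
polarity_state <- function(direction = c(1, 0, 0)) {
  d <- c(direction[1], direction[2], 0)
  n <- sqrt(sum(d^2))
  if (n == 0) stop("polarity direction must have a nonzero in-plane part")
  structure(list(direction = d / n), class = "polarity")
}

#' Identify leading-edge nodes
#'
#' A node is on the leading edge iff it (a) lies within the critical height
#' h_c of the substrate, (b) sits on the boundary ring of the contact region
#' (at least one mesh neighbor out of contact), (c) projects inside the
#' ligand pattern, and (d) in migration mode, has an outward in-plane normal
#' with a positive component along the polarity direction. Pass
#' `polarity = NULL` (spreading mode) to drop (d) and make protrusion
#' isotropic along the contact rim.
#'
#' @param cell cell [tri_mesh] with current differentials
#' @param field a [ligand_field]
#' @param polarity a [polarity_state] or `NULL`
#' @param h_c_nm contact height threshold (default 300)
#' @return integer vector of leading-edge node ids
#' @export
identify_leading_edge <- function(cell, field, polarity = NULL,
                                  h_c_nm = 300) {
  z <- cell$pos[, 3]
  contact <- z < h_c_nm
  if (!any(contact)) return(integer(0))
  nb <- cell$edges
  has_out <- logical(nrow(cell$pos))
  out1 <- contact[nb[, 1]] & !contact[nb[, 2]]
  out2 <- contact[nb[, 2]] & !contact[nb[, 1]]
  has_out[nb[out1, 1]] <- TRUE
  has_out[nb[out2, 2]] <- TRUE
  rim <- which(contact & has_out)
  keep <- vapply(rim, function(i) {
    tid <- field_locate(field, cell$pos[i, 1] / 1000, cell$pos[i, 2] / 1000)
    !is.na(tid) && field$mask[tid]
  }, logical(1))
  rim <- rim[keep]
  if (!is.null(polarity)) {
    nrm <- cell$node_normals[rim, , drop = FALSE]
    rim <- rim[nrm[, 1] * polarity$direction[1] +
                 nrm[, 2] * polarity$direction[2] > 0]
  }
  rim
}

#' Lamellipodium forces
#'
#' 300 pN along the outward in-plane normal (vertical component removed,
#' renormalized) at each leading-edge node; zero elsewhere.
#'
#' @param leading leading-edge node ids from [identify_leading_edge]
#' @param cell cell [tri_mesh]
#' @param F_L_pN protrusion force magnitude (default 300)
#' @return N x 3 force matrix, pN
#' @export
lamellipodium_forces <- function(leading, cell, F_L_pN = 300) {
  out <- matrix(0, nrow(cell$pos), 3)
  for (i in leading) {
    d <- c(cell$node_normals[i, 1], cell$node_normals[i, 2], 0)
    n <- sqrt(sum(d^2))
    if (n < 1e-12) next
    out[i, ] <- F_L_pN * d / n
  }
  out
}

#' Update the polarity direction from the recent nucleus track
#'
#' The new direction is the normalized in-plane nucleus displacement over the
#' recent track, perturbed by Gaussian angular noise (sigma 10 degrees per
#' update); displacements under 10 nm keep the previous direction (noise-free
#' persistence fallback).
#'
#' @param polarity a [polarity_state]
#' @param nucleus_track matrix of recent nucleus-center positions (nm), most
#'   recent last; at least 2 rows
#' @param sigma_deg angular noise SD per update (default 10)
#' @param min_disp_nm displacement below which the direction is kept
#'   (default 10)
#' @return the updated [polarity_state]
#' @export
update_polarity <- function(polarity, nucleus_track, sigma_deg = 10,
                            min_disp_nm = 10) {
  stopifnot(nrow(nucleus_track) >= 2)
  disp <- nucleus_track[nrow(nucleus_track), ] - nucleus_track[1, ]
  disp <- c(disp[1], disp[2])
  if (sqrt(sum(disp^2)) < min_disp_nm) return(polarity)
  ang <- atan2(disp[2], disp[1]) + stats::rnorm(1, 0, sigma_deg * pi / 180)
  polarity$direction <- c(cos(ang), sin(ang), 0)
  polarity
}
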