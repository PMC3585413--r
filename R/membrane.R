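#' Membrane elastic parameters
#'
#' Effective spring constants of the line (edge) and area elements of the two
#' membranes, and the friction coefficients of the overdamped dynamics.
#' Defaults (in pN/nm, converted from N/m): cell line 5.0e-5 N/m = 0.05,
#' nucleus line 5.0e-3 N/m = 5.0, both area constants 1.0e-4 N/m = 0.1.
#' Friction is 0.001 N s/m = 1 pN s/nm per node for both membranes.
#'
#' @param k_c_line,k_n_line line-element stiffness, cell / nucleus (pN/nm)
#' @param k_c_area,k_n_area area-element stiffness, cell / nucleus (pN/nm)
#' @param C_c,C_n node friction coefficients (pN s/nm)
#' @return list of class `elastic_params`
#' @export
elastic_params <- function(k_c_line = 0.05, k_n_line = 5.0,
                           k_c_area = 0.1, k_n_area = 0.1,
                           C_c = 1.0, C_n = 1.0) {
  stopifnot(k_c_line >= 0, k_n_line >= 0, k_c_area >= 0, k_n_area >= 0,
            C_c >= 0, C_n >= 0)
  structure(list(k_c_line = k_c_line, k_n_line = k_n_line,
                 k_c_area = k_c_area, k_n_area = k_n_area,
                 C_c = C_c, C_n = C_n), class = "elastic_params")
}

#' Elastic energy of the edge (line) network
#'
#' E = (k/2) sum_edges (L_i - L_i0)^2, a harmonic extension penalty on every
#' mesh edge relative to its relaxed length.
#'
#' @param mesh a [tri_mesh] with current differentials
#' @param k_line line stiffness, pN/nm
#' @return energy in pN nm
#' @export
line_energy <- function(mesh, k_line) {
  k_line / 2 * sum((mesh$edge_lengths - mesh$ref_edge_lengths)^2)
}

#' Elastic energy of the area elements
#'
#' E = (k/2) sum_triangles (A_i - A_i0)^2 / A_i0, a quadratic area-strain
#' penalty normalized by the relaxed area so the stiffness keeps pN/nm units.
#'
#' @param mesh a [tri_mesh] with current differentials
#' @param k_area area stiffness, pN/nm
#' @return energy in pN nm
#' @export
area_energy <- function(mesh, k_area) {
  k_area / 2 *
    sum((mesh$tri_areas - mesh$ref_tri_areas)^2 / mesh$ref_tri_areas)
}

#' Elastic forces on every mesh node
#'
#' Exact analytic negative gradient of the line + area elastic energy:
#' edge terms act along the edge direction, area terms through the analytic
#' area gradient of each incident triangle. Internal forces: the vector sum
#' over all nodes is zero.
#'
#' @param mesh a [tri_mesh] with current differentials
#' @param k_line,k_area stiffness constants, pN/nm
#' @return N x 3 matrix of forces, pN
#' @export
elastic_forces <- function(mesh, k_line, k_area) {
  elastic_forces_cpp(mesh$pos, mesh$edges - 1L, mesh$tris - 1L,
                     mesh$ref_edge_lengths, mesh$ref_tri_areas,
                     k_line, k_area)
}

#' Green-Lagrange surface strain at every node
#'
#' Per triangle, the 2-D deformation map from the stored reference
#' configuration to the current one gives F and E = (F^T F - I)/2; node
#' tensors are the area-weighted average of incident-triangle tensors pushed
#' into 3-D, projected onto the node tangent plane. Returns the in-plane
#' principal strains and the 3-D principal directions; the lower principal
#' direction (`dir_min`) steers ventral stress-fiber alignment toward the
#' stiffer (less stretched) axis.
#'
#' @param mesh a [tri_mesh] (reference configuration in `ref_pos`)
#' @return list with `e_min`, `e_max` (per-node principal strains) and
#'   `dir_min`, `dir_max` (N x 3 unit direction matrices)
#' @export
surface_strain <- function(mesh) {
  res <- surface_strain_cpp(mesh$pos, mesh$ref_pos, mesh$tris - 1L,
                            mesh$node_normals)
  names(res) <- c("e_min", "e_max", "dir_min", "dir_max")
  res
}
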