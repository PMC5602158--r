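# Conversion of cell-census tables (counts, regional placement fractions,
# normalized expression values) into per-region volumetric fields:
# chemokine production rates, total CCR7, ECM binding sites, and the ACKR4
# surface density on the capsule ceiling. Cell types are assumed uniformly
# distributed within each region, so all fields are piecewise constant.

PAREN_REGIONS <- c("BFOLLICLE", "TCELL_AREA", "MEDULLA")
CENSUS_QUANTITIES <- c("CCR7", "CCL19", "CCL21", "ECM", "ACKR4")

#' Per-cell maxima for census-derived quantities
#'
#' Maximum molecule numbers (or production rates) per cell used to scale
#' normalized expression values: 30,000 CCR7 and 30,000 ACKR4 molecules per
#' cell, 1e6 matrix binding sites per cell, and per-cell peak secretion
#' rates for CCL19/CCL21 (molecules/cell/s; calibrated defaults).
#'
#' @param CCR7,ACKR4 molecules per cell.
#' @param ECM binding sites per cell.
#' @param CCL19,CCL21 molecules secreted per cell per second.
#' @return named numeric vector.
#' @export
per_cell_maxima <- function(CCR7 = 30000, ACKR4 = 30000, ECM = 1e6,
                            CCL19 = 2.3, CCL21 = 7.6) {
  v <- c(CCR7 = CCR7, ACKR4 = ACKR4, ECM = ECM, CCL19 = CCL19, CCL21 = CCL21)
  if (any(v < 0)) stop("per_cell_maxima: all maxima must be >= 0")
  v
}

#' Read a cell-census table
#'
#' The census is a delimited text file with one row per cell type and
#' columns `cell_type`, `N` (total cells per whole node), `P_<REGION>`
#' (fraction of the type residing in each region) and `EV_<QUANTITY>`
#' (normalized expression values in `[0,1]` for CCR7, CCL19, CCL21, ECM,
#' ACKR4). The packaged default (`inst/extdata/cell_census.tsv`) carries
#' calibrated effective expression values chosen once so that the derived
#' regional fields reproduce reported lymph-node chemokine concentration
#' scales; it is an editable input, not a measurement.
#'
#' @param path file path; default is the packaged table.
#' @return a `data.frame` validated by [validate_census()].
#' @export
read_census <- function(path = system.file("extdata", "cell_census.tsv",
                                           package = "lnchemosim")) {
  cen <- utils::read.delim(path, sep = "\t", stringsAsFactors = FALSE,
                           check.names = FALSE)
  validate_census(cen)
}

#' @rdname read_census
#' @param census a census data.frame to validate.
#' @export
validate_census <- function(census) {
  need <- c("cell_type", "N",
            paste0("P_", PAREN_REGIONS), paste0("P_", "SCS"),
            paste0("EV_", CENSUS_QUANTITIES))
  miss <- setdiff(need, names(census))
  if (length(miss)) stop("census: missing columns: ", paste(miss, collapse = ", "))
  pcols <- grep("^P_", names(census), value = TRUE)
  P <- as.matrix(census[pcols])
  if (any(census$N < 0)) stop("census: cell counts must be >= 0")
  if (any(P < 0 | P > 1)) stop("census: region fractions must lie in [0,1]")
  if (any(rowSums(P) > 1 + 1e-9)) stop("census: region fractions sum to > 1")
  EV <- as.matrix(census[grep("^EV_", names(census), value = TRUE)])
  if (any(EV < 0 | EV > 1)) stop("census: expression values must lie in [0,1]")
  census
}

#' Regional concentration (or production rate) from the cell census
#'
#' For each region j the value is
#' `sum_k N_k * P_kj * EV_k * X_max / (N_A * Vol_j)`, converted to nM
#' (or nM/s for production quantities), with `Vol_j` the region volume
#' taken from the mesh. Cell counts are whole-node totals; since both the
#' moles and the volume scale by the quarter symmetry the concentration is
#' unchanged.
#'
#' @param census validated census table.
#' @param maxima named vector from [per_cell_maxima()].
#' @param quantity one of `"CCR7"`, `"CCL19"`, `"CCL21"`, `"ECM"`.
#' @param mesh an `ln_mesh` providing region volumes.
#' @return named vector of regional values (nM or nM/s), zero for regions
#'   with no cells of relevance (vessels, SCS for CCR7).
#' @export
concentration_from_census <- function(census, maxima, quantity, mesh) {
  stopifnot(quantity %in% CENSUS_QUANTITIES)
  census <- validate_census(census)
  regions <- names(REGIONS)
  vol_um3 <- mesh$region_vol * 4            # whole node volumes
  out <- setNames(numeric(length(regions)), regions)
  ev <- census[[paste0("EV_", quantity)]]
  for (rg in regions) {
    pcol <- paste0("P_", rg)
    if (!pcol %in% names(census)) next
    P <- census[[pcol]]
    if (all(P * ev * census$N == 0)) next
    if (vol_um3[[rg]] <= 0)
      stop("census: region ", rg, " has zero volume but a nonzero census")
    mol <- sum(census$N * P * ev) * maxima[[quantity]] / ln_units$avogadro
    out[[rg]] <- mol_in_um3_to_nM(mol, vol_um3[[rg]])
  }
  out
}

#' ACKR4 surface density on the capsule ceiling
#'
#' ACKR4 is expressed only by lymphatic endothelial cells lining the sinus
#' ceiling. With `ackr4_per_cell` receptors per LEC and a mean LEC diameter
#' `lec_diameter_um`, the surface density is receptors per LEC footprint,
#' ~61 molecules/um^2 at the defaults (30,000 / (pi * 12.5^2)). The same
#' LEC density is applied to the capsule over the medulla.
#'
#' @param maxima named vector from [per_cell_maxima()] (uses `ACKR4`).
#' @param lec_diameter_um mean ceiling LEC diameter (um, default 25).
#' @return surface density in molecules/um^2.
#' @export
ackr4_surface_density <- function(maxima = per_cell_maxima(),
                                  lec_diameter_um = 25) {
  maxima[["ACKR4"]] / (pi * (lec_diameter_um / 2)^2)
}

#' Assemble the regional field maps
#'
#' Builds the piecewise-constant fields needed by the transport solver:
#' CCL19/CCL21 production rates `q19`, `q21` (nM/s), total CCR7 `Rtot`
#' (nM), total matrix binding sites `Mtot` (nM), and the ACKR4 ceiling
#' surface density `Atot` (molecules/um^2). CCR7 is absent from the
#' vessels and the sinus.
#'
#' @param mesh an `ln_mesh`.
#' @param census census table (default: packaged table).
#' @param maxima per-cell maxima.
#' @param lec_diameter_um ceiling LEC diameter for the ACKR4 density.
#' @return object of class `ln_fields`: per-region named vectors and
#'   per-cell expansions.
#' @export
build_field_maps <- function(mesh, census = read_census(),
                             maxima = per_cell_maxima(),
                             lec_diameter_um = 25) {
  q19  <- concentration_from_census(census, maxima, "CCL19", mesh)
  q21  <- concentration_from_census(census, maxima, "CCL21", mesh)
  Rtot <- concentration_from_census(census, maxima, "CCR7", mesh)
  Mtot <- concentration_from_census(census, maxima, "ECM", mesh)
  # CCR7 carried only by parenchymal cells
  Rtot[c("AFFERENT_VESSEL", "SCS", "EFFERENT_VESSEL")] <- 0
  Atot <- ackr4_surface_density(maxima, lec_diameter_um)
  rg <- mesh$cell$region
  structure(list(
    region = list(q19 = q19, q21 = q21, Rtot = Rtot, Mtot = Mtot),
    cell = list(q19 = q19[rg], q21 = q21[rg], Rtot = Rtot[rg], Mtot = Mtot[rg]),
    Atot = Atot, census = census, maxima = maxima
  ), class = "ln_fields")
}

#' @export
print.ln_fields <- function(x, ...) {
  cat("Regional field maps (piecewise constant per region)\n")
  tab <- do.call(rbind, x$region)
  print(round(tab, 4))
  cat(sprintf("  ACKR4 ceiling density: %.3g molecules/um^2\n", x$Atot))
  invisible(x)
}
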