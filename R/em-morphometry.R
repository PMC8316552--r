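# Rule-based classification of annotated TEM vacuoles and per-cell
# morphometry. Vacuoles (>= 0.5 um) are autophagosomes (APG) when they
# meet two or more of four ultrastructural criteria (double membrane, no
# attached ribosomes, luminal density similar to the cytosol,
# identifiable organelles in the lumen); otherwise they are autolysosomes
# (AUT) when they meet at least one of three single-membrane criteria.

apg_criteria <- c("double_membrane", "no_attached_ribosomes",
                  "luminal_density_similar_to_cytosol",
                  "identifiable_organelles_in_lumen")
aut_criteria <- c("single_membrane_or_lt40pct_double",
                  "luminal_density_lower_than_cytosol",
                  "multivesicular_amorphous_content")

#' Classify annotated vacuoles
#'
#' Applies the decision rule to a table of per-vacuole annotations:
#' vacuoles below the size gate are `excluded`; else `APG` if at least two
#' APG criteria hold (the APG rule takes precedence); else `AUT` if at
#' least one AUT criterion holds; else `unclassified` (logged and excluded
#' from AV counts downstream).
#'
#' @param annotations data frame with `diameter_um` and the seven logical
#'   criterion columns (see [generate_vacuole_table()] for names).
#' @param size_gate_um minimum vacuole diameter in um (default 0.5).
#' @return the input with a `class` column added.
#' @export
classify_vacuoles <- function(annotations, size_gate_um = 0.5) {
  needed <- c("diameter_um", apg_criteria, aut_criteria)
  missing <- setdiff(needed, names(annotations))
  if (length(missing) > 0)
    stop("annotation table lacks column(s): ",
         paste(missing, collapse = ", "), call. = FALSE)
  if (any(annotations$diameter_um <= 0))
    stop("vacuole diameters must be positive", call. = FALSE)
  n_apg <- rowSums(as.matrix(annotations[apg_criteria]))
  n_aut <- rowSums(as.matrix(annotations[aut_criteria]))
  cls <- ifelse(annotations$diameter_um < size_gate_um, "excluded",
         ifelse(n_apg >= 2, "APG",
         ifelse(n_aut >= 1, "AUT", "unclassified")))
  both <- sum(cls == "APG" & n_aut >= 1)
  if (both > 0)
    aq_log("classify_vacuoles",
           "%d vacuole(s) met both rule sets; APG precedence applied",
           both, level = "DEBUG")
  if (any(cls == "unclassified"))
    aq_log("classify_vacuoles", "%d vacuole(s) matched neither rule",
           sum(cls == "unclassified"), level = "WARN")
  annotations$class <- cls
  annotations
}

#' Classify a single vacuole
#'
#' Scalar convenience wrapper around [classify_vacuoles()].
#' @param diameter_um vacuole diameter, um.
#' @param apg logical vector of length 4, the APG criteria.
#' @param aut logical vector of length 3, the AUT criteria.
#' @param size_gate_um minimum diameter (default 0.5).
#' @return one of `"APG"`, `"AUT"`, `"excluded"`, `"unclassified"`.
#' @export
classify_vacuole <- function(diameter_um, apg, aut, size_gate_um = 0.5) {
  stopifnot(length(apg) == 4, length(aut) == 3)
  df <- data.frame(diameter_um = diameter_um)
  for (j in 1:4) df[[apg_criteria[j]]] <- as.logical(apg[j])
  for (j in 1:3) df[[aut_criteria[j]]] <- as.logical(aut[j])
  classify_vacuoles(df, size_gate_um)$class
}

#' Per-cell autophagic-vacuole morphometry
#'
#' For each cell: counts of total autophagic vacuoles (AV = APG + AUT),
#' the fraction of the cell area occupied by AVs, the mean APG and AUT
#' areas, and the maturation percentages (%APG and %AUT of AV, which sum
#' to 100 whenever AV > 0). Excluded and unclassified vacuoles do not
#' contribute.
#'
#' @param annotations classified table (from [classify_vacuoles()]).
#' @param cell_areas data frame with `cell` and `cell_area_um2`.
#' @return data frame with one row per cell.
#' @export
morphometry_summary <- function(annotations, cell_areas) {
  if (is.null(annotations$class))
    stop("run classify_vacuoles() first (no `class` column)", call. = FALSE)
  stopifnot(all(c("cell", "cell_area_um2") %in% names(cell_areas)))
  unknown <- setdiff(unique(annotations$cell), cell_areas$cell)
  if (length(unknown) > 0)
    stop("no cell area for cell id(s): ", paste(unknown, collapse = ", "),
         call. = FALSE)
  out <- do.call(rbind, lapply(seq_len(nrow(cell_areas)), function(i) {
    cid <- cell_areas$cell[i]
    area <- cell_areas$cell_area_um2[i]
    v <- annotations[annotations$cell == cid &
                       annotations$class %in% c("APG", "AUT"), , drop = FALSE]
    n_apg <- sum(v$class == "APG"); n_aut <- sum(v$class == "AUT")
    av <- n_apg + n_aut
    data.frame(
      cell = cid, AV = av, APG = n_apg, AUT = n_aut,
      av_area_fraction = if (nrow(v) > 0) sum(v$area_um2) / area else 0,
      mean_apg_area = if (n_apg > 0) mean(v$area_um2[v$class == "APG"]) else NA_real_,
      mean_aut_area = if (n_aut > 0) mean(v$area_um2[v$class == "AUT"]) else NA_real_,
      pct_apg = if (av > 0) 100 * n_apg / av else NA_real_,
      pct_aut = if (av > 0) 100 * n_aut / av else NA_real_,
      stringsAsFactors = FALSE)
  }))
  rownames(out) <- NULL
  out
}
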