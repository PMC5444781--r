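#' Load a reef geomorphology typology at a chosen level
#'
#' Reads a typology table that assigns giant-clam density estimates
#' (ind ha^-1, mean and sd from field surveys) to reef geomorphological
#' classes at three nested levels: L1 treats all reef as a single habitat,
#' L2 separates shallow from variable-depth reef, and L3 distinguishes six
#' shallow geomorphological units. Densities for variable-depth classes are
#' derived from their shallow counterparts divided by one hundred when not
#' given explicitly (no field estimates exist at depth).
#'
#' @param file CSV path with columns
#'   `class_id,level3,level2,level1,depth_stratum,density_mean,density_sd`.
#'   One row per shallow L3 class, plus optional rows with empty `level3`
#'   (an L2-level pooled estimate) and empty `level2` (the L1 estimate).
#' @param level One of `"L3"`, `"L2"`, `"L1"`.
#' @return A `habitat_typology` tibble with columns `class_id`, `class_name`,
#'   `depth_stratum`, `density_mean`, `density_sd` and attributes `level` and
#'   `parent_map` (named character vector mapping each class to its class at
#'   the next coarser level; L1 maps to itself).
#' @export
load_typology <- function(file, level = c("L3", "L2", "L1")) {
  level <- match.arg(level)
  raw <- readr::read_csv(file, show_col_types = FALSE,
                         col_types = readr::cols(.default = "c"))
  need <- c("class_id", "level3", "level2", "level1", "depth_stratum",
            "density_mean", "density_sd")
  if (!all(need %in% names(raw))) {
    abort(paste0("typology file lacks columns: ",
                 paste(setdiff(need, names(raw)), collapse = ", ")))
  }
  raw <- raw %>%
    dplyr::mutate(density_mean = as.numeric(.data$density_mean),
                  density_sd = as.numeric(.data$density_sd))
  shallow3 <- raw %>% dplyr::filter(!is.na(.data$level3), .data$depth_stratum == "shallow")
  l2row <- raw %>% dplyr::filter(is.na(.data$level3), !is.na(.data$level2))
  l1row <- raw %>% dplyr::filter(is.na(.data$level3), is.na(.data$level2))
  if (nrow(shallow3) == 0) abort("typology file contains no shallow L3 classes")
  if (anyNA(shallow3$density_mean)) {
    abort(paste0("missing density for shallow class(es): ",
                 paste(shallow3$class_id[is.na(shallow3$density_mean)], collapse = ", ")))
  }
  if (any(c(raw$density_mean, raw$density_sd) < 0, na.rm = TRUE)) {
    abort("negative densities are not allowed")
  }

  hundredth <- function(tb, suffix, name_prefix) {
    tb %>% dplyr::mutate(
      class_id = paste0(.data$class_id, suffix),
      class_name = paste(name_prefix, .data$class_name),
      depth_stratum = "variable_depth",
      density_mean = .data$density_mean / 100,
      density_sd = .data$density_sd / 100
    )
  }

  if (level == "L3") {
    sh <- shallow3 %>%
      dplyr::transmute(class_id = .data$class_id, class_name = .data$level3,
                       depth_stratum = .data$depth_stratum,
                       density_mean = .data$density_mean,
                       density_sd = .data$density_sd)
    vd_given <- raw %>%
      dplyr::filter(!is.na(.data$level3), .data$depth_stratum == "variable_depth")
    vd <- if (nrow(vd_given) > 0) {
      vd_given %>% dplyr::transmute(class_id = .data$class_id,
                                    class_name = .data$level3,
                                    depth_stratum = .data$depth_stratum,
                                    density_mean = .data$density_mean,
                                    density_sd = .data$density_sd)
    } else hundredth(sh, "_vd", "Variable depth")
    classes <- dplyr::bind_rows(sh, vd)
    parent <- stats::setNames(
      c(rep("shallow_reefs", nrow(sh)), rep("variable_depth_reefs", nrow(vd))),
      classes$class_id)
  } else if (level == "L2") {
    if (nrow(l2row) == 0) abort("typology file has no L2-level density row")
    sh <- tibble(class_id = "shallow_reefs", class_name = l2row$level2[1],
                 depth_stratum = "shallow",
                 density_mean = l2row$density_mean[1],
                 density_sd = l2row$density_sd[1])
    vd <- hundredth(sh, "", "Variable depth") %>%
      dplyr::mutate(class_id = "variable_depth_reefs",
                    class_name = "Variable depth reef")
    classes <- dplyr::bind_rows(sh, vd)
    parent <- stats::setNames(rep("reef", 2), classes$class_id)
  } else {
    if (nrow(l1row) == 0) abort("typology file has no L1-level density row")
    classes <- tibble(class_id = "reef", class_name = l1row$level1[1],
                      depth_stratum = "all",
                      density_mean = l1row$density_mean[1],
                      density_sd = l1row$density_sd[1])
    parent <- c(reef = "reef")
  }
  if (anyNA(classes$density_mean)) abort("typology has classes without densities")
  new_typology(classes, level, parent)
}

new_typology <- function(classes, level, parent_map) {
  structure(as_tibble(classes), level = level, parent_map = parent_map,
            class = c("habitat_typology", class(as_tibble(classes))))
}

#' Built-in Tridacna maxima density typology
#'
#' The packaged density typology for *Tridacna maxima* on Southwest-Pacific
#' reefs (belt-transect survey estimates, six shallow geomorphological units;
#' variable-depth densities set a hundred-fold lower).
#'
#' @inheritParams load_typology
#' @return A `habitat_typology` tibble; see [load_typology()].
#' @export
#' @examples
#' reef_typology("L3")
reef_typology <- function(level = c("L3", "L2", "L1")) {
  load_typology(system.file("extdata", "tridacna_typology.csv",
                            package = "reefscape"),
                level = match.arg(level))
}

#' @export
print.habitat_typology <- function(x, ...) {
  cat("<habitat_typology> level", attr(x, "level"), "\n")
  NextMethod()
}

typology_level <- function(typology) attr(typology, "level")
typology_parent_map <- function(typology) attr(typology, "parent_map")

#' Sampling locations of the giant-clam genetic survey
#'
#' The 23 genetic sampling locations (site codes, names and number of
#' genotyped individuals) used throughout the package as the default shape
#' for synthetic "observed" datasets.
#'
#' @return A tibble with columns `site_code`, `site_name`, `n`.
#' @export
tridacna_sites <- function() {
  readr::read_csv(system.file("extdata", "tridacna_sites.csv",
                              package = "reefscape"),
                  show_col_types = FALSE)
}
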