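# Packaged machine-readable wardrobe: clothing items and ensembles with
# measured insulation / evaporative properties, loaders, audit and query.

ITEM_COLS <- c("item_id", "name", "brand_model", "size", "mass_g",
               "materials", "it", "fcl", "iclu", "body_region")
ENSEMBLE_COLS <- c("code", "composition", "group", "it", "fcl", "icl_si",
                   "icl_clo", "ret_raw", "ret", "recl", "im", "im_cl", "notes")
WET_COLS <- c("ret_raw", "ret", "recl", "im", "im_cl")

#' Load the wardrobe database
#'
#' Reads and validates the item and ensemble tables. The packaged default
#' holds 37 clothing items and 25 realistic ensembles of Dutch fire-service
#' station wear (operational uniform) and incident turnout gear, of which
#' 12 ensembles also carry evaporative (wet) measurements. The two
#' reference rows — the nude manikin (air layer, `AL`) and the bare textile
#' skin (`SK`, source of the air-layer evaporative resistance) — are split
#' out into `$reference`.
#'
#' Validation: required columns, unique ids, `fcl >= 1`, wet columns all
#' present or all absent per ensemble, and every composition id resolving
#' in the item table.
#'
#' @param items_path,ensembles_path CSV paths; defaults are the packaged
#'   tables.
#' @return An object of class `maniclo_wardrobe`: list with `items`
#'   (tibble, composition-eligible items), `ensembles` (tibble with
#'   list-column `composition`), and `reference` (the `AL` item row plus
#'   `AL`/`SK` ensemble rows).
#' @examples
#' wdb <- load_wardrobe()
#' nrow(wdb$items); nrow(wdb$ensembles)
#' @export
load_wardrobe <- function(items_path = NULL, ensembles_path = NULL) {
  if (is.null(items_path)) {
    items_path <- system.file("extdata", "items.csv", package = "maniclo")
  }
  if (is.null(ensembles_path)) {
    ensembles_path <- system.file("extdata", "ensembles.csv", package = "maniclo")
  }
  items <- tibble::as_tibble(utils::read.csv(
    items_path, colClasses = c(item_id = "character"), na.strings = ""))
  ens <- tibble::as_tibble(utils::read.csv(ensembles_path, na.strings = ""))

  miss <- setdiff(ITEM_COLS, names(items))
  if (length(miss) > 0L) stop("items table lacks column(s): ",
                              paste(miss, collapse = ", "), call. = FALSE)
  miss <- setdiff(ENSEMBLE_COLS, names(ens))
  if (length(miss) > 0L) stop("ensembles table lacks column(s): ",
                              paste(miss, collapse = ", "), call. = FALSE)
  if (anyDuplicated(items$item_id)) stop("duplicate item ids", call. = FALSE)
  if (anyDuplicated(ens$code)) stop("duplicate ensemble codes", call. = FALSE)

  check_row <- function(tab, id_col, val_col, lo) {
    bad <- which(!is.na(tab[[val_col]]) & tab[[val_col]] < lo)
    if (length(bad) > 0L) {
      stop(sprintf("%s below %g in row '%s', field '%s'", val_col, lo,
                   tab[[id_col]][bad[1L]], val_col), call. = FALSE)
    }
  }
  check_row(items, "item_id", "fcl", 1)
  check_row(items, "item_id", "it", 0)
  check_row(ens, "code", "fcl", 1)

  wet_counts <- rowSums(!is.na(ens[WET_COLS]))
  # the textile-skin row carries only ret_raw/ret by design
  partial <- ens$code[wet_counts > 0 & wet_counts < length(WET_COLS) &
                        ens$code != "SK"]
  if (length(partial) > 0L) {
    stop("wet fields must be all present or all absent; partial row(s): ",
         paste(partial, collapse = ", "), call. = FALSE)
  }

  ref_items <- items[items$body_region %in% "reference", ]
  items <- items[!items$body_region %in% "reference", ]
  ref_ens <- ens[ens$group %in% "reference", ]
  ens <- ens[!ens$group %in% "reference", ]

  comp <- lapply(ens$composition, function(s) {
    if (is.na(s) || !nzchar(s)) character(0) else strsplit(s, ";")[[1L]]
  })
  for (i in seq_along(comp)) {
    dangling <- setdiff(comp[[i]], items$item_id)
    if (length(dangling) > 0L) {
      stop(sprintf("ensemble %s references unknown item id(s): %s",
                   ens$code[i], paste(dangling, collapse = ", ")),
           call. = FALSE)
    }
  }
  ens$composition <- comp

  structure(list(items = items, ensembles = ens,
                 reference = list(items = ref_items, ensembles = ref_ens)),
            class = "maniclo_wardrobe")
}

#' @export
print.maniclo_wardrobe <- function(x, ...) {
  cat(sprintf("<maniclo_wardrobe> %d items, %d ensembles (%d with wet data)\n",
              nrow(x$items), nrow(x$ensembles),
              sum(!is.na(x$ensembles$ret))))
  invisible(x)
}

#' Write a wardrobe back to CSV
#'
#' Inverse of [load_wardrobe()]: reassembles the reference rows and the
#' semicolon-separated composition encoding so that a save/load round trip
#' reproduces the tables.
#'
#' @param wardrobe a `maniclo_wardrobe`.
#' @param dir output directory (created if absent).
#' @return Invisibly, the paths of the two files written.
#' @export
save_wardrobe <- function(wardrobe, dir) {
  stopifnot(inherits(wardrobe, "maniclo_wardrobe"))
  if (!dir.exists(dir)) dir.create(dir, recursive = TRUE)
  items <- rbind(wardrobe$reference$items, wardrobe$items)
  ens <- wardrobe$ensembles
  ens$composition <- vapply(ens$composition, paste, character(1), collapse = ";")
  ens$composition[ens$composition == ""] <- NA_character_
  ens <- rbind(wardrobe$reference$ensembles, ens)
  paths <- file.path(dir, c("items.csv", "ensembles.csv"))
  utils::write.csv(items, paths[1L], row.names = FALSE, na = "")
  utils::write.csv(ens, paths[2L], row.names = FALSE, na = "")
  invisible(paths)
}

#' Audit the internal consistency of a wardrobe
#'
#' Recomputes every derived column from its printed inputs — basic
#' insulation from I_T, f_cl and the nude air layer; the clo conversion;
#' clothing evaporative resistance from R_et, R_ea and f_cl; both
#' permeability indices — and reports the deviation of each against the
#' stored value. Published tables round derived columns computed from
#' unrounded inputs, so deviations up to one unit in the last printed digit
#' are expected; rows exceeding a tolerance are flagged, not dropped.
#'
#' @param wardrobe a `maniclo_wardrobe`.
#' @param tolerances named list: `insulation` (m2K/W), `clo`, `evap`
#'   (m2Pa/W), `index`.
#' @param ia,rea,lewis constants used in the recomputation; defaults come
#'   from the wardrobe's own reference rows when present.
#' @return A tibble (class `wardrobe_audit`) with columns `table`, `row`,
#'   `field`, `stored`, `recomputed`, `deviation`, `tolerance`, `pass`.
#' @examples
#' report <- audit_consistency(load_wardrobe())
#' subset(report, !pass)
#' @export
audit_consistency <- function(wardrobe,
                              tolerances = list(insulation = 0.0015,
                                                clo = 0.005,
                                                evap = 0.15,
                                                index = 0.015),
                              ia = NULL, rea = NULL,
                              lewis = maniclo_constants()$lewis) {
  stopifnot(inherits(wardrobe, "maniclo_wardrobe"))
  ref <- wardrobe$reference$ensembles
  if (is.null(ia)) {
    ia <- if (nrow(ref) && "AL" %in% ref$code) ref$it[ref$code == "AL"]
    else maniclo_constants()$ia
  }
  if (is.null(rea)) {
    rea <- if (nrow(ref) && "SK" %in% ref$code) ref$ret[ref$code == "SK"]
    else maniclo_constants()$rea
  }
  rows <- list()
  add <- function(table, row, field, stored, recomputed, tol) {
    keep <- !is.na(stored)
    if (!any(keep)) return()
    dev <- recomputed[keep] - stored[keep]
    rows[[length(rows) + 1L]] <<- tibble::tibble(
      table = table, row = row[keep], field = field,
      stored = stored[keep], recomputed = recomputed[keep],
      deviation = dev, tolerance = tol, pass = abs(dev) <= tol)
  }
  it <- wardrobe$items
  if (nrow(it)) {
    add("items", it$item_id, "iclu", it$iclu,
        it$it - ia / it$fcl, tolerances$insulation)
  }
  en <- wardrobe$ensembles
  if (nrow(en)) {
    add("ensembles", en$code, "icl_si", en$icl_si,
        en$it - ia / en$fcl, tolerances$insulation)
    add("ensembles", en$code, "icl_clo", en$icl_clo,
        to_clo(en$icl_si), tolerances$clo)
    add("ensembles", en$code, "recl", en$recl,
        en$ret - rea / en$fcl, tolerances$evap)
    add("ensembles", en$code, "im", en$im,
        en$it / (en$ret * lewis), tolerances$index)
    add("ensembles", en$code, "im_cl", en$im_cl,
        (en$it - ia / en$fcl) / ((en$ret - rea / en$fcl) * lewis),
        tolerances$index)
  }
  out <- if (length(rows)) do.call(rbind, rows) else tibble::tibble(
    table = character(), row = character(), field = character(),
    stored = numeric(), recomputed = numeric(), deviation = numeric(),
    tolerance = numeric(), pass = logical())
  class(out) <- c("wardrobe_audit", class(out))
  out
}

#' Query the wardrobe tables
#'
#' Filters either table by the supported keys and returns the subset in
#' stable id/code order.
#'
#' @param wardrobe a `maniclo_wardrobe`.
#' @param table `"ensembles"` or `"items"`.
#' @param body_region items only: body-region tag(s).
#' @param group ensembles only: `"operational_uniform"` or `"incident"`.
#' @param has_wet_data ensembles only: keep rows with (`TRUE`) / without
#'   (`FALSE`) evaporative measurements.
#' @param insulation_min,insulation_max bounds on total insulation `it`
#'   (m2K/W).
#' @return The filtered tibble; the number of rows is its count.
#' @examples
#' wardrobe_query(load_wardrobe(), has_wet_data = TRUE)
#' @export
wardrobe_query <- function(wardrobe, table = c("ensembles", "items"),
                           body_region = NULL, group = NULL,
                           has_wet_data = NULL,
                           insulation_min = NULL, insulation_max = NULL) {
  stopifnot(inherits(wardrobe, "maniclo_wardrobe"))
  table <- match.arg(table)
  tab <- wardrobe[[table]]
  if (table == "items") {
    if (!is.null(group) || !is.null(has_wet_data)) {
      stop("filters 'group' and 'has_wet_data' apply to ensembles only",
           call. = FALSE)
    }
    if (!is.null(body_region)) tab <- tab[tab$body_region %in% body_region, ]
    tab <- tab[order(tab$item_id), ]
  } else {
    if (!is.null(body_region)) {
      stop("filter 'body_region' applies to items only", call. = FALSE)
    }
    if (!is.null(group)) {
      group <- match.arg(group, c("operational_uniform", "incident"))
      tab <- tab[tab$group %in% group, ]
    }
    if (!is.null(has_wet_data)) {
      tab <- tab[xor(!has_wet_data, !is.na(tab$ret)), ]
    }
    tab <- tab[order(tab$code), ]
  }
  if (!is.null(insulation_min)) tab <- tab[tab$it >= insulation_min, ]
  if (!is.null(insulation_max)) tab <- tab[tab$it <= insulation_max, ]
  tab
}
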