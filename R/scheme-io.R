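# Resistance-scheme config files mirror the published table layout:
# one row per factor, five bin columns (resistance 10, 20, 30, 40, 50),
# one weight column. Continuous bins are interval strings like
# "[0, 3]" or "(3, 9]"; categorical bins are label lists separated by
# ";". The historical row label "Bo7" is accepted as "Bio7".

#' Read a resistance scheme from a table-layout CSV
#'
#' @param path CSV with columns `factor`, `r10`, `r20`, `r30`, `r40`,
#'   `r50`, `weight`.
#' @param lucc_legend optional named integer vector mapping categorical
#'   labels to raster codes (e.g. `c("Water area" = 4)`); without it,
#'   categorical bins keep a `label` column and must be mapped with
#'   [apply_category_legend()] before building a surface.
#' @return a [resistance_scheme()].
#' @export
read_resistance_scheme <- function(path, lucc_legend = NULL) {
  d <- utils::read.csv(path, stringsAsFactors = FALSE, check.names = FALSE)
  need <- c("factor", "r10", "r20", "r30", "r40", "r50", "weight")
  miss <- setdiff(need, names(d))
  if (length(miss))
    stop(sprintf("scheme file '%s' is missing column(s): %s", path,
                 paste(miss, collapse = ", ")))
  bins <- list()
  weights <- numeric(0)
  for (i in seq_len(nrow(d))) {
    fac <- d$factor[i]
    if (fac == "Bo7") fac <- "Bio7"   # historical typo in the source table
    levels <- c(10, 20, 30, 40, 50)
    cells <- as.character(d[i, c("r10", "r20", "r30", "r40", "r50")])
    if (all(grepl("^\\s*[\\[(]", cells))) {
      rows <- lapply(seq_along(cells), function(k) {
        iv <- parse_interval(cells[k], path, fac)
        data.frame(resistance = levels[k], lower = iv[1], upper = iv[2])
      })
      bins[[fac]] <- do.call(rbind, rows)
    } else {
      rows <- lapply(seq_along(cells), function(k) {
        labs <- trimws(strsplit(cells[k], ";")[[1]])
        labs <- labs[labs != ""]
        data.frame(resistance = rep(levels[k], length(labs)), label = labs,
                   stringsAsFactors = FALSE)
      })
      b <- do.call(rbind, rows)
      if (!is.null(lucc_legend)) {
        unknown <- setdiff(b$label, names(lucc_legend))
        if (length(unknown))
          stop(sprintf("scheme factor '%s': no legend code for '%s'", fac,
                       unknown[1]))
        b$code <- as.numeric(lucc_legend[b$label])
      }
      bins[[fac]] <- b
    }
    weights[[fac]] <- as.numeric(d$weight[i])
  }
  resistance_scheme(bins, weights)
}

parse_interval <- function(s, path, fac) {
  s <- gsub(",(?=\\d{3})", "", s, perl = TRUE)  # drop thousands separators
  m <- regmatches(s, regexec(
    "^\\s*[\\[(]\\s*(-?[0-9.eE+]+)\\s*,\\s*(-?[0-9.eE+]+)\\s*[\\])]\\s*$", s,
    perl = TRUE))[[1]]
  if (length(m) != 3)
    stop(sprintf("scheme file '%s', factor '%s': cannot parse interval '%s'",
                 path, fac, s))
  as.numeric(m[2:3])
}

#' Attach category codes to labelled scheme bins
#'
#' @param scheme a [resistance_scheme()] whose categorical factors carry
#'   `label` columns.
#' @param legend named integer vector, label -> raster code.
#' @return the scheme with `code` columns filled in.
#' @export
apply_category_legend <- function(scheme, legend) {
  for (v in names(scheme$bins)) {
    b <- scheme$bins[[v]]
    if ("label" %in% names(b) && !("code" %in% names(b))) {
      unknown <- setdiff(b$label, names(legend))
      if (length(unknown))
        stop(sprintf("factor '%s': no legend code for '%s'", v, unknown[1]))
      b$code <- as.numeric(legend[b$label])
      scheme$bins[[v]] <- b
    }
  }
  scheme
}

#' Write a resistance scheme as a table-layout CSV
#'
#' @param scheme a [resistance_scheme()].
#' @param path output CSV path.
#' @return `path`, invisibly.
#' @export
write_resistance_scheme <- function(scheme, path) {
  rows <- lapply(names(scheme$bins), function(v) {
    b <- scheme$bins[[v]]
    cells <- vapply(c(10, 20, 30, 40, 50), function(lv) {
      bb <- b[b$resistance == lv, , drop = FALSE]
      if (!nrow(bb)) return("")
      if ("lower" %in% names(bb)) {
        paste(sprintf("(%g, %g]", bb$lower, bb$upper), collapse = "; ")
      } else if ("label" %in% names(bb)) {
        paste(bb$label, collapse = "; ")
      } else paste(sprintf("%g", bb$code), collapse = "; ")
    }, "")
    data.frame(factor = v, r10 = cells[1], r20 = cells[2], r30 = cells[3],
               r40 = cells[4], r50 = cells[5],
               weight = scheme$weights[[v]], stringsAsFactors = FALSE)
  })
  utils::write.csv(do.call(rbind, rows), path, row.names = FALSE)
  invisible(path)
}
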