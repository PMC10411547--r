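#' Default map style
#'
#' Colour codes follow the conventions of comparative trait maps in the
#' Solanaceae literature: dark green for oomycete resistance, light green
#' fungi, purple bacteria, blue viruses, magenta nematodes, red insects,
#' orange sugar-content QTL, yellow weight/yield QTL, maroon maturity QTL.
#' Layout: tomato map on the left, potato on the right, dotted pairing
#' lines between them, red dotted lines inside translocated segments.
#'
#' @param extra named character vector of additional trait-class colours.
#' @return list of class `map_style`.
#' @export
map_style <- function(extra = NULL) {
  class_colour <- c(oomycete = "#006400", fungus = "#66BB44",
                    bacterium = "#800080", virus = "#0000CC",
                    nematode = "#CC00CC", insect = "#CC0000",
                    sugar = "#EE8800", yield = "#DDCC00",
                    weight = "#DDCC00", maturity = "#800000")
  if (!is.null(extra)) class_colour[names(extra)] <- extra
  structure(list(class_colour = class_colour,
                 px_per_mbp = 120, axis_gap = 420, margin = 60,
                 label_step = 13), class = "map_style")
}

locus_colour <- function(trait_class, style, scheme = default_nomenclature()) {
  pc <- pathogen_class_of(trait_class, scheme)
  key <- ifelse(is.na(pc), trait_class, pc)
  col <- style$class_colour[key]
  unname(ifelse(is.na(col), "#555555", col))
}

#' Summarize named loci per trait class and species
#'
#' @param loci locus table after [assign_names()] and [filter_large()].
#' @return data frame: trait_class, species, n_loci (excluded-large loci
#'   counted separately in `n_excluded`), min/max/mean interval width in
#'   Mbp (1 decimal).
#' @export
summarize_loci <- function(loci) {
  if (!nrow(loci))
    return(data.frame(trait_class = character(), species = character(),
                      n_loci = integer(), n_excluded = integer(),
                      min_mbp = numeric(), max_mbp = numeric(),
                      mean_mbp = numeric(), stringsAsFactors = FALSE))
  if (is.null(loci$excluded_large)) loci$excluded_large <- FALSE
  key <- paste(loci$trait_class, loci$species, sep = "|")
  res <- lapply(sort(unique(key)), function(k) {
    g <- loci[key == k, , drop = FALSE]
    kept <- g[!g$excluded_large, , drop = FALSE]
    w <- (kept$end - kept$start) / 1e6
    data.frame(trait_class = g$trait_class[1], species = g$species[1],
               n_loci = nrow(kept), n_excluded = sum(g$excluded_large),
               min_mbp = if (nrow(kept)) round(min(w), 1) else NA_real_,
               max_mbp = if (nrow(kept)) round(max(w), 1) else NA_real_,
               mean_mbp = if (nrow(kept)) round(mean(w), 1) else NA_real_,
               stringsAsFactors = FALSE)
  })
  do.call(rbind, c(res, make.row.names = FALSE))
}

svg_esc <- function(x) {
  x <- gsub("&", "&amp;", x, fixed = TRUE)
  x <- gsub("<", "&lt;", x, fixed = TRUE)
  gsub(">", "&gt;", x, fixed = TRUE)
}

# greedy downward displacement of label y positions, deterministic in
# start-coordinate order
displace_labels <- function(y, step) {
  if (!length(y)) return(y)
  o <- order(y, seq_along(y))
  out <- y
  last <- -Inf
  for (i in o) {
    out[i] <- max(y[i], last + step)
    last <- out[i]
  }
  out
}

#' Render a dual-chromosome trait map as SVG
#'
#' Two vertical Mbp-scaled axes (genome B / tomato on the left, genome A /
#' potato on the right); quantitative loci as colour-coded side bars with
#' the star-suffixed uniform name; sequence-characterized genes as a
#' single tick, interval-mapped genes as two boundary ticks; one dotted
#' connector per comparison pair, drawn red when the pair lies inside an
#' intra-chromosomal translocation call. Output is deterministic: fixed
#' ordering, no timestamps.
#'
#' @param chrom chromosome name.
#' @param lociA,lociB named locus tables for the right (A) and left (B)
#'   map; only rows on `chrom` are allowed (others are an error).
#' @param pairs optional comparison-pair table (chromA, posA, posB).
#' @param calls optional rearrangement-call table.
#' @param chrom_len_a,chrom_len_b chromosome lengths in bp.
#' @param style [map_style()].
#' @param scheme nomenclature scheme (for pathogen-class colours).
#' @return single SVG character string.
#' @export
render_map <- function(chrom, lociA = NULL, lociB = NULL, pairs = NULL,
                       calls = NULL, chrom_len_a, chrom_len_b = chrom_len_a,
                       style = map_style(),
                       scheme = default_nomenclature()) {
  for (l in list(lociA, lociB))
    if (!is.null(l) && nrow(l) && any(l$chrom != chrom))
      stop("locus on wrong chromosome for map of ", chrom)
  px <- function(bp) round(style$margin +
                             bp / 1e6 * style$px_per_mbp, 1)
  xL <- style$margin + 120          # left (B) axis
  xR <- xL + style$axis_gap         # right (A) axis
  h <- px(max(chrom_len_a, chrom_len_b)) + style$margin
  w <- xR + 260
  out <- c(sprintf(
    '<svg xmlns="http://www.w3.org/2000/svg" width="%d" height="%d">',
    w, round(h)),
    sprintf('<title>%s</title>', svg_esc(chrom)))
  # axes and Mbp ticks
  tick <- max(1, round(max(chrom_len_a, chrom_len_b) / 1e6 / 10))
  axis <- function(x, len, side) {
    seg <- sprintf('<line x1="%d" y1="%s" x2="%d" y2="%s" stroke="black" stroke-width="3"/>',
                   x, px(0), x, px(len))
    tk <- seq(0, len / 1e6, by = tick)
    lab <- sprintf(
      '<line x1="%d" y1="%s" x2="%d" y2="%s" stroke="black"/><text x="%d" y="%s" font-size="10" text-anchor="%s">%s</text>',
      x, px(tk * 1e6), x + ifelse(side == "L", -5, 5), px(tk * 1e6),
      x + ifelse(side == "L", -8, 8), px(tk * 1e6) + 3,
      ifelse(side == "L", "end", "start"), format(tk))
    c(seg, lab)
  }
  out <- c(out, axis(xL, chrom_len_b, "L"), axis(xR, chrom_len_a, "R"))

  draw_side <- function(loci, x, side) {
    if (is.null(loci) || !nrow(loci)) return(character())
    if (!is.null(loci$excluded_large))
      loci <- loci[!loci$excluded_large, , drop = FALSE]
    if (!nrow(loci)) return(character())
    loci <- loci[order(loci$start, loci$end, loci$name), , drop = FALSE]
    sgn <- ifelse(side == "L", -1, 1)
    xb <- x + sgn * 14
    xt <- x + sgn * 60
    ylab <- displace_labels(px((loci$start + loci$end) / 2),
                            style$label_step)
    el <- character()
    for (i in seq_len(nrow(loci))) {
      col <- locus_colour(loci$trait_class[i], style, scheme)
      y0 <- px(loci$start[i]); y1 <- px(loci$end[i])
      lab <- svg_esc(paste0(loci$name[i],
                            if (!is.null(loci$star)) loci$star[i] else ""))
      if (loci$locus_kind[i] == "qualitative") {
        # gene: single tick for point-like placement, two border ticks for
        # an interval
        if (loci$end[i] - loci$start[i] <= 1e4) {
          el <- c(el, sprintf(
            '<line x1="%d" y1="%s" x2="%s" y2="%s" stroke="black"/>',
            x, y0, xb, y0))
        } else {
          el <- c(el, sprintf(
            '<line x1="%d" y1="%s" x2="%s" y2="%s" stroke="black"/>',
            x, y0, xb, y0), sprintf(
            '<line x1="%d" y1="%s" x2="%s" y2="%s" stroke="black"/>',
            x, y1, xb, y1))
        }
      } else {
        el <- c(el, sprintf(
          '<rect x="%s" y="%s" width="6" height="%s" fill="%s"/>',
          min(xb, xb + sgn * 6), y0, max(0.5, round(y1 - y0, 1)), col))
      }
      el <- c(el, sprintf(
        '<line x1="%s" y1="%s" x2="%s" y2="%s" stroke="%s" stroke-width="0.5"/>',
        xb + sgn * 6, (y0 + y1) / 2, xt, ylab[i], col), sprintf(
        '<text x="%s" y="%s" font-size="10" fill="%s" text-anchor="%s">%s</text>',
        xt + sgn * 3, ylab[i] + 3, col,
        ifelse(side == "L", "end", "start"), lab))
    }
    el
  }
  out <- c(out, draw_side(lociB, xL, "L"), draw_side(lociA, xR, "R"))

  if (!is.null(pairs) && nrow(pairs)) {
    p <- pairs[pairs$chromA == chrom, , drop = FALSE]
    p <- p[order(p$posA, p$posB), , drop = FALSE]
    in_transloc <- rep(FALSE, nrow(p))
    if (!is.null(calls) && nrow(calls)) {
      tr <- calls[calls$kind == "intra_translocation" &
                    calls$chrom == chrom, , drop = FALSE]
      for (i in seq_len(nrow(tr)))
        in_transloc <- in_transloc |
          (p$posA >= tr$startA[i] & p$posA <= tr$endA[i])
    }
    out <- c(out, sprintf(
      '<line x1="%d" y1="%s" x2="%d" y2="%s" stroke="%s" stroke-width="0.6" stroke-dasharray="2,3"/>',
      xL, px(p$posB), xR, px(p$posA),
      ifelse(in_transloc, "red", "#777777")))
  }
  out <- c(out, "</svg>")
  paste(out, collapse = "\n")
}

#' Render an anchor-order dotplot for one chromosome as SVG
#'
#' Visual audit of the collinear chaining: posA against posB, backbone
#' pairs in grey, off-backbone pairs coloured by call kind.
#'
#' @param pairs matched pairs on one chromosome.
#' @param calls rearrangement calls on the chromosome.
#' @param chrom chromosome name.
#' @param size plot edge in px.
#' @return SVG string.
#' @export
render_dotplot <- function(pairs, calls, chrom, size = 400) {
  p <- pairs[pairs$chromA == chrom, , drop = FALSE]
  if (!nrow(p)) return(sprintf(
    '<svg xmlns="http://www.w3.org/2000/svg" width="%d" height="%d"/>',
    size, size))
  mA <- max(p$posA); mB <- max(p$posB)
  x <- round(20 + p$posA / mA * (size - 40), 1)
  y <- round(size - 20 - p$posB / mB * (size - 40), 1)
  col <- rep("#888888", nrow(p))
  if (!is.null(calls) && nrow(calls)) {
    cc <- calls[calls$chrom == chrom, , drop = FALSE]
    for (i in seq_len(nrow(cc))) {
      sel <- p$posA >= cc$startA[i] & p$posA <= cc$endA[i]
      col[sel] <- if (cc$kind[i] == "inversion") "#CC0000" else "#0000CC"
    }
  }
  paste(c(sprintf(
    '<svg xmlns="http://www.w3.org/2000/svg" width="%d" height="%d">',
    size, size),
    sprintf('<title>%s</title>', svg_esc(chrom)),
    sprintf('<circle cx="%s" cy="%s" r="1.5" fill="%s"/>', x, y, col),
    "</svg>"), collapse = "\n")
}
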