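# Readers and writers: the native TSV layout exchange format, a minimal
# VARNA-style SVG subset reader, and SVG / PostScript output with
# insert/relabel/shift color coding.
#
# All writers are deterministic: numbers are printed as the shortest decimal
# of their 6-significant-digit rounding, so identical inputs give
# byte-identical files. File formats use 0-based residue indices.

fmt_num <- function(x) {
  out <- vapply(x, function(v) {
    if (!is.finite(v)) stop("non-finite number in output")
    if (abs(v) < 1e-9) return("0")
    s <- format(signif(v, 6), scientific = FALSE, trim = TRUE)
    if (s == "-0") "0" else s
  }, character(1))
  out
}

STATUS_CODES <- c(unchanged = "u", shifted = "s", relabeled = "r", inserted = "i")

COLOR_OF <- c(unchanged = "#000000", shifted = "#0000FF",
              relabeled = "#008000", inserted = "#FF0000")
OVERLAP_COLOR <- "#FF00FF"

# ---- layout TSV -------------------------------------------------------------

#' Write / read the TSV layout exchange format
#'
#' The native template-layout format: two header comment lines (format
#' version; geometry constants), a column comment, then one tab-separated
#' record per residue: 0-based index, letter, x, y, 0-based partner index
#' (or -1 if unpaired), and a status code (u/s/r/i for
#' unchanged/shifted/relabeled/inserted). Records are sorted by index and
#' contiguous from 0; the partner relation must be symmetric.
#'
#' @param doc An [template_document()].
#' @param path File path.
#' @return `read_layout_tsv()` returns an `rna_template`;
#'   `write_layout_tsv()` returns `path` invisibly.
#' @export
write_layout_tsv <- function(doc, path) {
  g <- doc$geom
  lay <- doc$layout
  L <- nrow(lay)
  partner0 <- ifelse(is.na(lay$partner), -1L, lay$partner - 1L)
  lines <- c("# rnalayout layout v1",
             sprintf("# geometry backbone_step=%s pair_step=%s bond_length=%s",
                     fmt_num(g$backbone_step), fmt_num(g$pair_step),
                     fmt_num(g$bond_length)),
             "# index letter x y partner status",
             sprintf("%d\t%s\t%s\t%s\t%d\t%s",
                     seq_len(L) - 1L, lay$letter, fmt_num(lay$x), fmt_num(lay$y),
                     partner0, STATUS_CODES[lay$status]))
  writeLines(lines, path)
  invisible(path)
}

#' @rdname write_layout_tsv
#' @export
read_layout_tsv <- function(path) {
  lines <- readLines(path, warn = FALSE)
  lines <- sub("\r$", "", lines)
  geom <- default_geometry()
  gl <- grep("^# geometry ", lines, value = TRUE)
  if (length(gl) >= 1L) {
    for (kv in strsplit(sub("^# geometry ", "", gl[1L]), " +")[[1L]]) {
      p <- strsplit(kv, "=", fixed = TRUE)[[1L]]
      if (length(p) == 2L && p[1L] %in% names(geom)) {
        geom[[p[1L]]] <- as.numeric(p[2L])
      }
    }
  }
  body_ln <- which(!startsWith(lines, "#") & nzchar(trimws(lines)))
  if (length(body_ln) == 0L) stop("layout parse error: no residues")
  rec <- strsplit(lines[body_ln], "\t", fixed = TRUE)
  bad <- which(lengths(rec) != 6L)
  if (length(bad) > 0L) {
    stop("layout parse error at line ", body_ln[bad[1L]],
         ": expected 6 tab-separated fields")
  }
  m <- do.call(rbind, rec)
  idx <- suppressWarnings(as.integer(m[, 1L]))
  x <- suppressWarnings(as.numeric(m[, 3L]))
  y <- suppressWarnings(as.numeric(m[, 4L]))
  partner <- suppressWarnings(as.integer(m[, 5L]))
  for (col in list(idx, x, y, partner)) {
    if (anyNA(col)) {
      stop("layout parse error at line ", body_ln[which(is.na(col))[1L]],
           ": malformed number")
    }
  }
  L <- length(idx)
  if (!identical(idx, seq_len(L) - 1L)) {
    off <- which(idx != seq_len(L) - 1L)[1L]
    stop("layout parse error at line ", body_ln[off],
         ": indices must be contiguous from 0")
  }
  st_code <- m[, 6L]
  st <- names(STATUS_CODES)[match(st_code, STATUS_CODES)]
  if (anyNA(st)) {
    stop("layout parse error at line ", body_ln[which(is.na(st))[1L]],
         ": unknown status code")
  }
  partner1 <- ifelse(partner < 0L, NA_integer_, partner + 1L)
  for (k in seq_len(L)) {
    p <- partner1[k]
    if (!is.na(p)) {
      if (p < 1L || p > L || is.na(partner1[p]) || partner1[p] != k) {
        stop("layout parse error: asymmetric partner between lines ",
             body_ln[k], " and ", body_ln[min(max(p, 1L), L)])
      }
    }
  }
  pr <- which(!is.na(partner1) & seq_len(L) < partner1)
  ss <- rna_structure(m[, 2L], cbind(pr, partner1[pr]))
  ss2 <- remove_pseudoknots(ss)
  if (nrow(ss2$pairs) != nrow(ss$pairs)) stop("layout parse error: crossing pairs")
  template_document(ss, data.frame(x = x, y = y, status = st),
                    backbone_step = geom$backbone_step,
                    pair_step = geom$pair_step, bond_length = geom$bond_length)
}

# ---- SVG --------------------------------------------------------------------

#' Write an SVG drawing of a layout
#'
#' One text glyph per residue (y flipped to the screen-down SVG convention),
#' one line per base pair, and the backbone rendered as short connector
#' segments with a gap around the glyphs. With `colored = TRUE` glyphs are
#' colored by status: inserted red, relabeled green, shifted blue, otherwise
#' black. With `overlaps = TRUE` crossing segments are re-drawn highlighted
#' and the count is stored in a `data-overlaps` attribute.
#'
#' @param doc An [template_document()].
#' @param path Output path.
#' @param colored Color glyphs by status flag.
#' @param overlaps Highlight crossing segments.
#' @return `path`, invisibly.
#' @export
write_svg <- function(doc, path, colored = FALSE, overlaps = FALSE) {
  lay <- doc$layout
  g <- doc$geom
  margin <- 2 * g$backbone_step
  yflip <- max(lay$y) + margin          # svg y = yflip - internal y
  x0 <- min(lay$x) - margin
  X <- lay$x - x0
  Y <- yflip - lay$y
  W <- max(X) + margin
  H <- max(Y) + margin
  fs <- fmt_num(0.8 * g$backbone_step)
  out <- c(sprintf(paste0('<svg xmlns="http://www.w3.org/2000/svg" version="1.1" ',
                          'width="%s" height="%s" data-yflip="%s" data-xshift="%s" ',
                          'data-backbone-step="%s" data-pair-step="%s" data-bond-length="%s">'),
                   fmt_num(W), fmt_num(H), fmt_num(yflip), fmt_num(x0),
                   fmt_num(g$backbone_step), fmt_num(g$pair_step),
                   fmt_num(g$bond_length)))
  segline <- function(r1, r2, class, color, width) {
    p1 <- c(X[r1], Y[r1]); p2 <- c(X[r2], Y[r2])
    d <- vnorm(p2 - p1)
    if (class == "backbone") {
      gap <- 0.28 * g$backbone_step     # keep clear of the glyphs
      if (d <= 2.2 * gap) return(character(0))
      u <- (p2 - p1) / d
      p1 <- p1 + gap * u; p2 <- p2 - gap * u
    }
    sprintf('<line class="%s" x1="%s" y1="%s" x2="%s" y2="%s" stroke="%s" stroke-width="%s"/>',
            class, fmt_num(p1[1L]), fmt_num(p1[2L]), fmt_num(p2[1L]),
            fmt_num(p2[2L]), color, fmt_num(width))
  }
  L <- nrow(lay)
  for (r in seq_len(L - 1L)) {
    out <- c(out, segline(r, r + 1L, "backbone", "#808080", 0.6))
  }
  p <- doc$structure$pairs
  for (a in seq_len(nrow(p))) {
    out <- c(out, segline(p[a, 1L], p[a, 2L], "bond", "#000000", 0.9))
  }
  ov_count <- 0L
  if (overlaps) {
    rep <- count_overlaps(doc)
    ov_count <- rep$count
    cr <- rep$crossings
    for (a in seq_len(nrow(cr))) {
      out <- c(out, segline(cr$i1[a], cr$j1[a], "overlap", OVERLAP_COLOR, 1.5),
               segline(cr$i2[a], cr$j2[a], "overlap", OVERLAP_COLOR, 1.5))
    }
    out[1L] <- sub("data-yflip", sprintf('data-overlaps="%d" data-yflip', ov_count),
                   out[1L], fixed = TRUE)
  }
  fill <- if (colored) COLOR_OF[lay$status] else rep("#000000", L)
  out <- c(out, sprintf(paste0('<text x="%s" y="%s" fill="%s" font-size="%s" ',
                               'text-anchor="middle" dominant-baseline="middle" ',
                               'font-family="monospace">%s</text>'),
                        fmt_num(X), fmt_num(Y), fill, fs, lay$letter),
           "</svg>")
  writeLines(out, path)
  invisible(path)
}

#' Read a minimal VARNA-style SVG template
#'
#' Recovers a template document from an SVG containing one text glyph per
#' residue (5' to 3' in document order) and one line element per base pair;
#' line endpoints are matched to the nearest residue centers. Lines whose
#' class marks them as backbone or overlap decoration are ignored, so the
#' output of [write_svg()] reads back as the same document. A line endpoint
#' further than `0.5 * backbone_step` from every glyph is an error.
#'
#' @param path SVG file path.
#' @return An `rna_template`.
#' @export
read_varna_svg <- function(path) {
  xml <- tryCatch(xml2::read_xml(path), error = function(e) {
    stop("not an SVG/XML document: ", conditionMessage(e))
  })
  if (xml2::xml_name(xml) != "svg") stop("not an SVG document (root is <",
                                         xml2::xml_name(xml), ">)")
  geom <- default_geometry()
  att <- function(name, default) {
    v <- xml2::xml_attr(xml, name)
    if (is.na(v)) default else as.numeric(v)
  }
  geom$backbone_step <- att("data-backbone-step", geom$backbone_step)
  geom$pair_step <- att("data-pair-step", geom$pair_step)
  geom$bond_length <- att("data-bond-length", geom$bond_length)
  yflip <- att("data-yflip", 0)
  x0 <- att("data-xshift", 0)
  texts <- xml2::xml_find_all(xml, ".//*[local-name()='text']")
  if (length(texts) == 0L) stop("no residue glyphs found")
  gx <- as.numeric(xml2::xml_attr(texts, "x")) + x0
  gy <- yflip - as.numeric(xml2::xml_attr(texts, "y"))
  letters <- trimws(xml2::xml_text(texts))
  if (any(nchar(letters) != 1L)) stop("glyphs must hold single residue letters")
  lines <- xml2::xml_find_all(xml, ".//*[local-name()='line']")
  cls <- xml2::xml_attr(lines, "class")
  keep <- is.na(cls) | !(cls %in% c("backbone", "overlap"))
  lines <- lines[keep]
  nearest <- function(px, py) {
    d2 <- (gx - px)^2 + (gy - py)^2
    k <- which.min(d2)
    if (sqrt(d2[k]) > 0.5 * geom$backbone_step) {
      stop("line endpoint (", fmt_num(px), ", ", fmt_num(py),
           ") matches no residue glyph")
    }
    k
  }
  pairs <- matrix(integer(0), ncol = 2L)
  for (ln in lines) {
    x1 <- as.numeric(xml2::xml_attr(ln, "x1")) + x0
    y1 <- yflip - as.numeric(xml2::xml_attr(ln, "y1"))
    x2 <- as.numeric(xml2::xml_attr(ln, "x2")) + x0
    y2 <- yflip - as.numeric(xml2::xml_attr(ln, "y2"))
    if (anyNA(c(x1, y1, x2, y2))) stop("line element with malformed coordinates")
    a <- nearest(x1, y1); b <- nearest(x2, y2)
    if (a == b) stop("degenerate base-pair line at glyph ", a - 1L)
    pairs <- rbind(pairs, c(min(a, b), max(a, b)))
  }
  ss <- rna_structure(letters, pairs)
  template_document(ss, data.frame(x = gx, y = gy),
                    backbone_step = geom$backbone_step,
                    pair_step = geom$pair_step, bond_length = geom$bond_length)
}

# ---- PostScript -------------------------------------------------------------

#' Write a PostScript drawing of a layout
#'
#' Mirror of [write_svg()] in PostScript level 1 (y up, native PS
#' convention): `moveto`/`lineto`/`stroke` for bonds and backbone
#' connectors, `moveto`/`show` for residue glyphs, `setrgbcolor` for the
#' status colors when `colored = TRUE`.
#'
#' @inheritParams write_svg
#' @return `path`, invisibly.
#' @export
write_ps <- function(doc, path, colored = FALSE) {
  lay <- doc$layout
  g <- doc$geom
  margin <- 2 * g$backbone_step
  X <- lay$x - min(lay$x) + margin
  Y <- lay$y - min(lay$y) + margin
  rgb_of <- function(hex) {
    v <- grDevices::col2rgb(hex) / 255
    paste(fmt_num(v[1L]), fmt_num(v[2L]), fmt_num(v[3L]))
  }
  out <- c("%!PS-Adobe-3.0",
           sprintf("%%%%BoundingBox: 0 0 %s %s",
                   fmt_num(max(X) + margin), fmt_num(max(Y) + margin)),
           sprintf("/Courier findfont %s scalefont setfont",
                   fmt_num(0.8 * g$backbone_step)),
           "0 0 0 setrgbcolor")
  seg <- function(r1, r2, trim) {
    p1 <- c(X[r1], Y[r1]); p2 <- c(X[r2], Y[r2])
    if (trim) {
      d <- vnorm(p2 - p1)
      gap <- 0.28 * g$backbone_step
      if (d <= 2.2 * gap) return(character(0))
      u <- (p2 - p1) / d
      p1 <- p1 + gap * u; p2 <- p2 - gap * u
    }
    sprintf("%s %s moveto %s %s lineto stroke",
            fmt_num(p1[1L]), fmt_num(p1[2L]), fmt_num(p2[1L]), fmt_num(p2[2L]))
  }
  L <- nrow(lay)
  for (r in seq_len(L - 1L)) out <- c(out, seg(r, r + 1L, TRUE))
  p <- doc$structure$pairs
  for (a in seq_len(nrow(p))) out <- c(out, seg(p[a, 1L], p[a, 2L], FALSE))
  for (r in seq_len(L)) {
    col <- if (colored) COLOR_OF[lay$status[r]] else "#000000"
    out <- c(out, sprintf("%s setrgbcolor", rgb_of(col)),
             sprintf("%s %s moveto (%s) show",
                     fmt_num(X[r]), fmt_num(Y[r]), lay$letter[r]))
  }
  out <- c(out, "showpage")
  writeLines(out, path)
  invisible(path)
}
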