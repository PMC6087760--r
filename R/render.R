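# Rendering of figures and complete items, plus answer-key export.

rot2 <- function(xy, deg) {
  th <- deg * pi / 180
  R <- matrix(c(cos(th), sin(th), -sin(th), cos(th)), 2, 2)
  xy %*% t(R)
}

#' Concrete geometry of a figure state
#'
#' Resolves an `fa_state` against a template into drawable coordinates: the
#' transformed outline and corner positions, the present internal-line
#' segments, the dot position, the broken-circle arc, and the trapezium
#' polygon.  The main-shape transform is flip (about the x axis) first, then
#' counterclockwise rotation by 45 * (main - 1) degrees; the trapezium sits
#' at its own anchor angle 45 * (trap - 1) degrees, independent of the main
#' shape.
#'
#' @param state An `fa_state`.
#' @param template An `fa_template`.
#' @return A list of coordinate sets used by the drawing code.
#' @export
figure_geometry <- function(state, template = fa_template()) {
  tf <- function(xy) {
    if (state$flip) xy <- cbind(xy[, 1], -xy[, 2])
    rot2(xy, 45 * (state$main - 1))
  }
  corners <- tf(template$corners)
  outline <- tf(template$outline)

  segs <- lapply(state$lines, function(i) {
    rbind(corners[template$lines[i, 1], ], corners[template$lines[i, 2], ])
  })

  bc <- template$broken_circle
  bc_center_t <- colMeans(template$corners[bc$corners, , drop = FALSE]) * 1.25
  ang <- seq(bc$gap_deg / 2, 360 - bc$gap_deg / 2, length.out = 40) * pi / 180
  arc_t <- cbind(bc_center_t[1] + bc$radius * cos(ang),
                 bc_center_t[2] + bc$radius * sin(ang))
  arc <- tf(arc_t)

  trap_angle <- 45 * (state$trap - 1) - 90  # state 1 sits below the shape
  anchor <- template$trapezium$anchor_radius *
    c(cos(trap_angle * pi / 180), sin(trap_angle * pi / 180))
  trap_poly <- rot2(template$trapezium$poly, trap_angle + 90)
  trap_poly <- cbind(trap_poly[, 1] + anchor[1], trap_poly[, 2] + anchor[2])

  list(corners = corners, outline = outline, segments = segs,
       dot = corners[state$dot, ], arc = arc, trapezium = trap_poly)
}

draw_figure <- function(state, template, label = NULL, cex = 1) {
  geo <- figure_geometry(state, template)
  graphics::plot.new()
  graphics::plot.window(xlim = c(-1.55, 1.55), ylim = c(-1.55, 1.55), asp = 1)
  graphics::polygon(geo$outline, border = "grey65", lwd = 1)
  for (s in geo$segments) graphics::lines(s, lwd = 2)
  graphics::lines(geo$arc, lwd = 1.5)
  graphics::polygon(geo$trapezium, border = "black", col = "grey85", lwd = 1.5)
  graphics::points(geo$dot[1], geo$dot[2], pch = 19, cex = 1.3 * cex)
  if (!is.null(label)) {
    graphics::text(-1.4, 1.4, label, font = 2, cex = 1.2 * cex)
  }
  graphics::box(col = "grey80")
}

draw_question_mark <- function(cex = 1) {
  graphics::plot.new()
  graphics::plot.window(xlim = c(-1.55, 1.55), ylim = c(-1.55, 1.55), asp = 1)
  graphics::text(0, 0, "?", cex = 4 * cex)
  graphics::box(col = "grey80")
}

#' Verbal option strings
#'
#' The wording of the two verbal options ("no answer is correct", keyed as
#' position 9, and "I don't know") in the supported languages.
#'
#' @param language `"E"` (English), `"D"` (German) or `"S"` (Spanish).
#' @return Named character vector with entries `none_correct` and
#'   `dont_know`.
#' @export
verbal_options <- function(language = c("E", "D", "S")) {
  language <- match.arg(language)
  switch(language,
    E = c(none_correct = "no answer is correct", dont_know = "I don't know"),
    D = c(none_correct = "Keine Antwort ist richtig", dont_know = "Ich weiß es nicht"),
    S = c(none_correct = "Ninguna respuesta es correcta", dont_know = "No lo sé")
  )
}

#' Render one item on the current graphics device
#'
#' Draws the stem (A, B, C and the blank D slot) and the eight figural
#' options in reading order (left to right, top down), followed by the two
#' verbal options in the configured language.  Three arrangements are
#' available: mode `"A"` (stem row above a 4 x 2 options grid, the layout
#' with empirical support), mode `"B"` (stem row above a 2 x 4 grid) and
#' mode `"C"` (a compact two-row arrangement).
#'
#' @param item An `fa_item`.
#' @param mode Plot mode, `"A"` (default), `"B"` or `"C"`.
#' @param language Verbal-option language, `"E"`, `"D"` or `"S"`.
#' @param form_int,form_ext Template presets, see [fa_template()].
#' @return Invisibly, the item.
#' @export
render_item <- function(item, mode = c("A", "B", "C"),
                        language = c("E", "D", "S"),
                        form_int = "A", form_ext = "A") {
  mode <- match.arg(mode)
  language <- match.arg(language)
  if (!inherits(item, "fa_item")) stop_invalid("`item` must be an `fa_item`")
  template <- fa_template(form_int, form_ext)
  vo <- verbal_options(language)

  op <- graphics::par(no.readonly = TRUE)
  on.exit(graphics::par(op), add = TRUE)
  graphics::par(mar = c(0.3, 0.3, 0.3, 0.3), oma = c(0, 0, 1.6, 0))

  lay <- switch(mode,
    A = graphics::layout(
      rbind(c(1, 2, 3, 4), c(5, 6, 7, 8), c(9, 10, 11, 12), c(13, 13, 13, 13)),
      heights = c(1.15, 1, 1, 0.35)),
    B = graphics::layout(
      rbind(c(1, 2, 3, 4), c(5, 5, 6, 6), c(7, 7, 8, 8), c(9, 9, 10, 10),
            c(11, 11, 12, 12), c(13, 13, 13, 13)),
      heights = c(1.1, 1, 1, 1, 1, 0.4)),
    C = graphics::layout(
      rbind(c(1, 2, 3, 4, 5, 6), c(7, 8, 9, 10, 11, 12), c(13, 13, 13, 13, 13, 13)),
      heights = c(1, 1, 0.35))
  )
  cexf <- if (mode == "C") 0.8 else 1

  stem <- item$stem
  draw_figure(stem$A, template, "A", cexf)
  draw_figure(stem$B, template, "B", cexf)
  draw_figure(stem$C, template, "C", cexf)
  draw_question_mark(cexf)

  for (i in 1:8) {
    draw_figure(item$options$states[[i]], template, as.character(i), 0.9 * cexf)
  }

  graphics::plot.new()
  graphics::plot.window(xlim = c(0, 1), ylim = c(0, 1))
  graphics::text(0.5, 0.55,
                 sprintf("(9) %s        (0) %s", vo["none_correct"], vo["dont_know"]),
                 cex = 1.05 * cexf)
  graphics::mtext(sprintf("Item %d", item$isomorph_index), outer = TRUE,
                  cex = 0.9, line = 0.2)
  invisible(item)
}

#' Plot items of a bank
#'
#' Renders the selected items one device page at a time and (optionally)
#' prints the relevant information: the general rules applied and the
#' correct answer of every plotted item.
#'
#' @param x An `fa_item_bank`.
#' @param which Indices of the items to plot (default: all).
#' @param mode,language,form_int,form_ext See [render_item()].
#' @param info Print rules and correct answers (default `TRUE`).
#' @param ... Unused.
#' @return Invisibly, the answer-key data frame of the plotted items.
#' @export
plot.fa_item_bank <- function(x, which = NULL, mode = "A", language = "E",
                              form_int = "A", form_ext = "A", info = TRUE, ...) {
  which <- check_which(x, which)
  for (i in which) {
    render_item(x$items[[i]], mode = mode, language = language,
                form_int = form_int, form_ext = form_ext)
  }
  key <- answer_key(x, which)
  if (info) {
    print(key)
  }
  invisible(key)
}

check_which <- function(bank, which) {
  n <- length(bank$items)
  if (is.null(which)) return(seq_len(n))
  if (!(is.numeric(which) && all(which == round(which)) &&
        all(which >= 1 & which <= n)))
    stop_invalid("`which` must index existing items (1..%d)", n)
  as.integer(which)
}

#' Answer key of a bank
#'
#' @param bank An `fa_item_bank`.
#' @param which Item indices (default: all).
#' @return A data frame with `item_id`, `correct_position` (1..9, options
#'   read left to right and top down; 9 is the "no answer is correct"
#'   option) and `rules_used` (general-rule names, semicolon-joined).
#' @export
answer_key <- function(bank, which = NULL) {
  which <- check_which(bank, which)
  data.frame(
    item_id = sprintf("item%02d", which),
    correct_position = vapply(bank$items[which], function(it)
      it$correct_position, integer(1)),
    rules_used = vapply(bank$items[which], function(it)
      paste(it$rules_used, collapse = ";"), character(1)),
    stringsAsFactors = FALSE
  )
}

#' Export a bank as PNG files plus a CSV answer key
#'
#' Writes one PNG per selected item and language, and (when `info` is kept
#' `TRUE`) a CSV answer key naming every exported item's correct position
#' and general rules.
#'
#' @inheritParams plot.fa_item_bank
#' @param bank An `fa_item_bank`.
#' @param directory Existing, writable output directory.
#' @param language_dir Languages to export, subset of `c("E", "D", "S")`.
#' @param width,height PNG size in pixels.
#' @return A data frame manifest of the written files (`path`, `type`),
#'   invisibly.
#' @export
export_bank <- function(bank, directory, which = NULL, mode = "A",
                        language_dir = c("E", "D", "S"),
                        form_int = "A", form_ext = "A", info = TRUE,
                        width = 880, height = 990) {
  if (!inherits(bank, "fa_item_bank")) stop_invalid("`bank` must be an `fa_item_bank`")
  if (!dir.exists(directory))
    fa_stop("fa_io", "output directory '%s' does not exist", directory)
  language_dir <- match.arg(language_dir, several.ok = TRUE)
  which <- check_which(bank, which)
  if (length(which) == 0L) stop_invalid("empty item selection")
  paths <- character(0); types <- character(0)
  for (i in which) {
    for (lang in language_dir) {
      path <- file.path(directory, sprintf("item%02d_%s.png", i, lang))
      grDevices::png(path, width = width, height = height)
      ok <- tryCatch({
        render_item(bank$items[[i]], mode = mode, language = lang,
                    form_int = form_int, form_ext = form_ext)
        TRUE
      }, finally = grDevices::dev.off())
      paths <- c(paths, path); types <- c(types, "image")
    }
  }
  if (info) {
    key_path <- file.path(directory, "answer_key.csv")
    utils::write.csv(answer_key(bank, which), key_path, row.names = FALSE,
                     fileEncoding = "UTF-8")
    paths <- c(paths, key_path); types <- c(types, "key")
  }
  invisible(data.frame(path = paths, type = types, stringsAsFactors = FALSE))
}

#' Swap two response options of an item
#'
#' Exchanges the options at two slots (1..8) and keeps the answer key
#' consistent: if the correct answer sat on one of the two slots, its
#' recorded position follows it.
#'
#' @param x An `fa_item`, or an `fa_item_bank` together with `which`.
#' @param from,to Slot positions in 1..8.
#' @param which For a bank: the index of the item to modify.
#' @return The modified item or bank.
#' @examples
#' b <- build_analogies(mirror = 1, correct = 3, seed = 1)
#' b2 <- switch_options(b, from = 3, to = 7, which = 1)
#' b2$items[[1]]$correct_position  # 7
#' @export
switch_options <- function(x, from, to, which = NULL) {
  if (inherits(x, "fa_item_bank")) {
    which <- check_which(x, which)
    if (length(which) != 1L)
      stop_invalid("`which` must name exactly one item of the bank")
    x$items[[which]] <- switch_options(x$items[[which]], from, to)
    return(x)
  }
  if (!inherits(x, "fa_item")) stop_invalid("`x` must be an `fa_item` or `fa_item_bank`")
  if (!is_count(from, 1L) || from > 8 || !is_count(to, 1L) || to > 8)
    stop_invalid("`from` and `to` must be positions in 1..8")
  from <- as.integer(from); to <- as.integer(to)
  if (from == to) return(x)
  st <- x$options$states
  st[c(from, to)] <- st[c(to, from)]
  x$options$states <- st
  cb <- x$options$combos
  cb[c(from, to), ] <- cb[c(to, from), , drop = FALSE]
  x$options$combos <- cb
  cp <- x$correct_position
  if (cp == from) cp <- to else if (cp == to) cp <- from
  x$correct_position <- cp
  x$options$correct_position <- cp
  x
}
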