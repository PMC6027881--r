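#' Specify a view window
#'
#' The graph layout shows a main panel plus two overview selectors: the
#' bottom plot selects an x (degree) subrange across all replicons, the
#' right plot a y (replicon) subrange. A `view_spec` captures one such
#' selection.
#'
#' @param x_range Numeric length-2, degrees, within `[0, 360]`.
#' @param y_range Integer length-2, replicon indices, lower bound >= 1.
#' @param show_vectors,show_segments Toggle drawing of gene vectors and
#'   alignment segments.
#' @return A `blastxy_view` object.
#' @export
view_spec <- function(x_range = c(0, 360), y_range = NULL,
                      show_vectors = TRUE, show_segments = TRUE) {
  if (length(x_range) != 2 || any(!is.finite(x_range))) {
    abort("x_range must be two finite numbers")
  }
  if (x_range[1] > x_range[2]) {
    abort("inverted x_range")
  }
  if (x_range[1] < 0 || x_range[2] > 360) {
    abort("x_range must lie within [0, 360]")
  }
  if (!is.null(y_range)) {
    if (length(y_range) != 2 || any(!is.finite(y_range))) {
      abort("y_range must be two finite numbers")
    }
    if (y_range[1] > y_range[2]) {
      abort("inverted y_range")
    }
    if (y_range[1] < 1) {
      abort("y_range lower bound must be >= 1")
    }
  }
  structure(
    list(x_range = as.numeric(x_range), y_range = y_range,
         show_vectors = isTRUE(show_vectors),
         show_segments = isTRUE(show_segments)),
    class = "blastxy_view"
  )
}

#' The default browsing zoom: a 25-degree window
#'
#' A named preset matching the typical way of browsing results: select a
#' range of around 25 degrees on the x axis and drag across it.
#'
#' @param x_start Left edge of the window in degrees.
#' @param y_range Optional replicon index range.
#' @return A `blastxy_view` spanning `[x_start, x_start + 25]`.
#' @export
zoom25 <- function(x_start = 0, y_range = NULL) {
  view_spec(c(x_start, min(360, x_start + 25)), y_range)
}

# degree intervals covered by each result's vector; origin-wrapping vectors
# yield a second interval reduced to [0, 360)
vector_intervals <- function(results) {
  x0 <- pmin(results$x, results$x + results$vector_deg)
  x1 <- pmax(results$x, results$x + results$vector_deg)
  list(lo = x0, hi = x1)
}

#' Select the rows visible in a view
#'
#' A result is visible when any part of its vector intersects the x range
#' (not only its dot -- long genes must not vanish when their origin sits
#' just outside a zoomed window) and its replicon index lies in the y
#' range. Origin-wrapping vectors are checked on both sides of the 360/0
#' seam.
#'
#' @param results Plotted-result tibble.
#' @param view A [view_spec()].
#' @return The visible rows, original order preserved.
#' @export
select_view <- function(results, view = view_spec()) {
  if (!inherits(view, "blastxy_view")) {
    abort("view must be created with view_spec()")
  }
  if (nrow(results) == 0) return(results)
  iv <- vector_intervals(results)
  xr <- view$x_range
  hit_x <- iv$lo <= xr[2] & iv$hi >= xr[1]
  wrapped <- iv$hi > 360
  if (any(wrapped)) {
    hit_x[wrapped] <- hit_x[wrapped] |
      (0 <= xr[2] & (iv$hi[wrapped] - 360) >= xr[1])
  }
  keep <- hit_x
  if (!is.null(view$y_range)) {
    keep <- keep & results$y >= view$y_range[1] & results$y <= view$y_range[2]
  }
  results[keep, , drop = FALSE]
}

# ---- static SVG -----------------------------------------------------------

svg_esc <- function(x) {
  x <- gsub("&", "&amp;", x, fixed = TRUE)
  x <- gsub("<", "&lt;", x, fixed = TRUE)
  gsub(">", "&gt;", x, fixed = TRUE)
}

# overview summaries: result counts per 1-degree x bin and per replicon row
overview_bins <- function(rows, n_y) {
  xbin <- pmin(359L, as.integer(floor(rows$x %% 360)))
  xs <- tabulate(xbin + 1L, nbins = 360L)
  ys <- tabulate(rows$y, nbins = n_y)
  list(x = xs, y = ys)
}

#' Render the three-panel graph as a static SVG
#'
#' Draws the main panel (one dot, one strand-aware vector and one thicker
#' bit-score-coloured alignment segment per visible result), a bottom
#' x-overview and a right y-overview showing result densities, and a colour
#' legend. Output is deterministic: identical input yields identical bytes.
#'
#' Marks carry `class` attributes (`dot`, `vector`, `segment`) so the
#' element tree can be inspected programmatically.
#'
#' @param results Plotted-result tibble (projected and capped).
#' @param view A [view_spec()].
#' @param path Output path for the SVG file.
#' @param width,height Canvas size in pixels.
#' @return `path`, invisibly.
#' @export
render_static <- function(results, view = view_spec(), path,
                          width = 1000, height = 600) {
  check_results(results)
  dir <- dirname(path)
  if (!dir.exists(dir)) {
    abort(paste0("cannot write SVG: directory not found: ", dir))
  }
  n_y <- max(1, suppressWarnings(max(results$y, -Inf)),
             view$y_range[2] %||% 1)
  visible <- select_view(results, view)
  xr <- view$x_range
  yr <- view$y_range %||% c(1, n_y)

  # panel geometry: main | right overview; bottom overview under main
  m <- list(left = 60, top = 30, right_w = 90, bottom_h = 80, gap = 20)
  main_w <- width - m$left - m$right_w - 3 * m$gap
  main_h <- height - m$top - m$bottom_h - 3 * m$gap
  px <- function(x) m$left + (x - xr[1]) / max(xr[2] - xr[1], 1e-9) * main_w
  py <- function(y) {
    span <- max(yr[2] - yr[1] + 1, 1)
    m$top + main_h - (y - yr[1] + 0.5) / span * main_h
  }

  el <- character()
  add <- function(...) el[[length(el) + 1]] <<- paste0(...)

  add(sprintf(
    '<svg xmlns="http://www.w3.org/2000/svg" version="1.1" width="%d" height="%d" viewBox="0 0 %d %d">',
    width, height, width, height
  ))
  add('<rect width="100%" height="100%" fill="white"/>')
  add(sprintf('<rect class="main-panel" x="%d" y="%d" width="%.2f" height="%.2f" fill="none" stroke="#888"/>',
              m$left, m$top, main_w, main_h))

  # axis annotations
  for (t in pretty(xr, 6)) {
    if (t < xr[1] || t > xr[2]) next
    add(sprintf('<line class="x-tick" x1="%.2f" y1="%.2f" x2="%.2f" y2="%.2f" stroke="#888"/>',
                px(t), m$top + main_h, px(t), m$top + main_h + 4))
    add(sprintf('<text class="x-label" x="%.2f" y="%.2f" font-size="10" text-anchor="middle">%s</text>',
                px(t), m$top + main_h + 16, fmt_num(t)))
  }
  y_ticks <- unique(round(pretty(yr, min(6, yr[2] - yr[1] + 1))))
  for (t in y_ticks) {
    if (t < yr[1] || t > yr[2]) next
    add(sprintf('<text class="y-label" x="%.2f" y="%.2f" font-size="10" text-anchor="end">%d</text>',
                m$left - 6, py(t) + 3, as.integer(t)))
  }
  add(sprintf('<text class="axis-title" x="%.2f" y="%.2f" font-size="11" text-anchor="middle">relative position (degrees)</text>',
              m$left + main_w / 2, m$top + main_h + 30))

  if (nrow(visible) > 0) {
    for (i in seq_len(nrow(visible))) {
      r <- visible[i, ]
      x0 <- px(r$x); y0 <- py(r$y)
      x1 <- px(r$x + r$vector_deg)
      sgn <- if (r$vector_deg >= 0) 1 else -1
      s0 <- px(r$x + sgn * r$seg_offset_deg)
      s1 <- px(r$x + sgn * (r$seg_offset_deg + r$seg_len_deg))
      col <- bitscore_to_color(r$bitscore, attr(results, "scale") %||%
                                 color_scale(min(results$bitscore),
                                             max(results$bitscore)))
      if (view$show_vectors) {
        add(sprintf('<line class="vector" x1="%.3f" y1="%.3f" x2="%.3f" y2="%.3f" stroke="#555" stroke-width="1"/>',
                    x0, y0, x1, y0))
      }
      if (view$show_segments) {
        add(sprintf('<line class="segment" x1="%.3f" y1="%.3f" x2="%.3f" y2="%.3f" stroke="rgb(%d,%d,%d)" stroke-width="3"/>',
                    s0, y0, s1, y0, col$r, col$g, col$b))
      }
      add(sprintf('<circle class="dot" cx="%.3f" cy="%.3f" r="2.5" fill="black"/>',
                  x0, y0))
    }
  }

  # bottom x-overview: counts per degree bin
  ob <- overview_bins(tibble::as_tibble(results), n_y)
  oy <- m$top + main_h + m$gap + 20
  max_xc <- max(ob$x, 1)
  bw <- main_w / 360
  for (b in which(ob$x > 0)) {
    h <- ob$x[b] / max_xc * (m$bottom_h - 25)
    add(sprintf('<rect class="x-overview-bar" x="%.2f" y="%.2f" width="%.2f" height="%.2f" fill="#4477aa"/>',
                m$left + (b - 1) * bw, oy + (m$bottom_h - 25) - h, bw, h))
  }
  add(sprintf('<rect class="x-overview" x="%d" y="%.2f" width="%.2f" height="%.2f" fill="none" stroke="#888"/>',
              m$left, oy, main_w, m$bottom_h - 25))

  # right y-overview: counts per replicon
  ox <- m$left + main_w + m$gap
  max_yc <- max(ob$y, 1)
  rh <- main_h / n_y
  for (b in which(ob$y > 0)) {
    w <- ob$y[b] / max_yc * (m$right_w - 10)
    add(sprintf('<rect class="y-overview-bar" x="%.2f" y="%.2f" width="%.2f" height="%.2f" fill="#4477aa"/>',
                ox, m$top + main_h - b * rh + rh * 0.1, w, rh * 0.8))
  }
  add(sprintf('<rect class="y-overview" x="%.2f" y="%d" width="%.2f" height="%.2f" fill="none" stroke="#888"/>',
              ox, m$top, m$right_w - 10, main_h))

  # colour legend: scale endpoints
  add(sprintf('<defs><linearGradient id="bs"><stop offset="0" stop-color="rgb(255,255,0)"/><stop offset="1" stop-color="rgb(0,0,139)"/></linearGradient></defs>'))
  add(sprintf('<rect class="legend" x="%.2f" y="%.2f" width="120" height="10" fill="url(#bs)" stroke="#888"/>',
              m$left, height - 18))
  add(sprintf('<text class="legend-label" x="%.2f" y="%.2f" font-size="10">BitScore: least %s significant %s most</text>',
              m$left + 126, height - 10, "&#8594;", "&#8594;"))
  add('</svg>')
  writeLines(el, path)
  invisible(path)
}

# ---- interactive HTML -----------------------------------------------------

# fields of the per-mark hover payload (basic info popup) and the
# additional click payload (text-box detail)
hover_fields <- c("rel_position", "bitscore", "query", "organism", "product")
click_fields <- c("subject_id", "replicon_id", "evalue", "s_start", "s_end")

embedded_data_json <- function(results, view) {
  rows <- tibble::as_tibble(results)
  data <- purrr::pmap(rows, function(...) {
    r <- list(...)
    list(
      x = r$x, y = r$y, vector_deg = r$vector_deg, strand = r$strand,
      seg_offset_deg = r$seg_offset_deg, seg_len_deg = r$seg_len_deg,
      bitscore = r$bitscore, color_value = r$color_value,
      evalue = r$evalue, query_id = r$query_id, subject_id = r$subject_id,
      organism = r$organism, product = r$product,
      replicon_id = r$replicon_id, s_start = r$s_start, s_end = r$s_end,
      hover = list(
        rel_position = r$x, bitscore = r$bitscore, query = r$query_id,
        organism = r$organism, product = r$product
      ),
      click = list(
        subject_id = r$subject_id, replicon_id = r$replicon_id,
        evalue = r$evalue, s_start = r$s_start, s_end = r$s_end
      )
    )
  })
  obj <- list(
    view = list(x_range = view$x_range,
                y_range = view$y_range %||% c(1, max(1, max(rows$y, 0)))),
    results = data
  )
  jsonlite::toJSON(obj, auto_unbox = TRUE, digits = NA, null = "null")
}

#' Render the graph as a self-contained interactive HTML document
#'
#' A single-file HTML page with the three-panel layout: a zoomable,
#' draggable main plot, a bottom x-range selector, a right y-range
#' selector, and a detail text box. Hovering a mark pops up its basic
#' information (relative position, BitScore, query header, organism, gene
#' product); clicking shows the additional detail (subject id, replicon,
#' e-value, subject coordinates) in the text box.
#'
#' All data is embedded as a JSON island (`<script id="blastxy-data">`)
#' whose `results` array equals the capped result set, so re-rendering the
#' same input is byte-identical.
#'
#' @param results Plotted-result tibble (projected).
#' @param view Initial [view_spec()].
#' @param path Output path for the HTML file.
#' @param display_cap Maximum number of embedded results (default 50,000).
#' @param title Page title.
#' @return `path`, invisibly.
#' @export
render_interactive <- function(results, view = view_spec(), path,
                               display_cap = 50000, title = "blastxy graph") {
  check_results(results)
  if (nrow(results) > display_cap) {
    results <- apply_result_cap(results, display_cap)
  }
  data_json <- embedded_data_json(results, view)
  html <- c(
    "<!DOCTYPE html>",
    "<html><head><meta charset=\"utf-8\">",
    paste0("<title>", svg_esc(title), "</title>"),
    "<style>",
    "body{font-family:sans-serif;margin:12px}",
    "#layout{display:grid;grid-template-columns:1fr 110px;gap:8px;max-width:1100px}",
    "canvas{border:1px solid #888;background:#fff}",
    "#detail{border:1px solid #888;padding:6px;min-height:3em;grid-column:1/3;font-size:13px;white-space:pre-line}",
    "#tip{position:fixed;display:none;background:#ffe;border:1px solid #885;padding:4px;font-size:12px;pointer-events:none}",
    "</style></head><body>",
    paste0("<h3>", svg_esc(title), "</h3>"),
    "<div id=\"layout\">",
    "<canvas id=\"main\" width=\"900\" height=\"420\"></canvas>",
    "<canvas id=\"yov\" width=\"100\" height=\"420\"></canvas>",
    "<canvas id=\"xov\" width=\"900\" height=\"80\"></canvas>",
    "<div></div>",
    "<div id=\"detail\">Click a result for details.</div>",
    "</div>",
    "<div id=\"tip\"></div>",
    paste0("<script id=\"blastxy-data\" type=\"application/json\">",
           data_json, "</script>"),
    "<script>", interactive_js(), "</script>",
    "</body></html>"
  )
  writeLines(html, path)
  invisible(path)
}

interactive_js <- function() {
  # minimal pan/zoom/hover engine over the embedded JSON island
  paste(c(
    "var D=JSON.parse(document.getElementById('blastxy-data').textContent);",
    "var R=D.results,V={x0:D.view.x_range[0],x1:D.view.x_range[1],",
    " y0:D.view.y_range[0],y1:D.view.y_range[1]};",
    "var M=document.getElementById('main'),C=M.getContext('2d');",
    "var XO=document.getElementById('xov'),XC=XO.getContext('2d');",
    "var YO=document.getElementById('yov'),YC=YO.getContext('2d');",
    "function px(x){return (x-V.x0)/(V.x1-V.x0)*M.width;}",
    "function py(y){var s=V.y1-V.y0+1;return M.height-(y-V.y0+0.5)/s*M.height;}",
    "function col(v){var r=Math.round(255*(1-v)),g=Math.round(255*(1-v)),b=Math.round(139*v);return 'rgb('+r+','+g+','+b+')';}",
    "function draw(){C.clearRect(0,0,M.width,M.height);",
    " for(var i=0;i<R.length;i++){var r=R[i];",
    "  var lo=Math.min(r.x,r.x+r.vector_deg),hi=Math.max(r.x,r.x+r.vector_deg);",
    "  if(hi<V.x0||lo>V.x1||r.y<V.y0||r.y>V.y1)continue;",
    "  var y=py(r.y),s=r.vector_deg>=0?1:-1;",
    "  C.strokeStyle='#555';C.lineWidth=1;C.beginPath();",
    "  C.moveTo(px(r.x),y);C.lineTo(px(r.x+r.vector_deg),y);C.stroke();",
    "  C.strokeStyle=col(r.color_value);C.lineWidth=3;C.beginPath();",
    "  C.moveTo(px(r.x+s*r.seg_offset_deg),y);",
    "  C.lineTo(px(r.x+s*(r.seg_offset_deg+r.seg_len_deg)),y);C.stroke();",
    "  C.fillStyle='#000';C.beginPath();C.arc(px(r.x),y,2.5,0,6.2832);C.fill();}}",
    "function overviews(){XC.clearRect(0,0,XO.width,XO.height);",
    " var xb=new Array(360).fill(0),yb={};var ymax=1;",
    " for(var i=0;i<R.length;i++){xb[Math.min(359,Math.floor(R[i].x%360))]++;",
    "  yb[R[i].y]=(yb[R[i].y]||0)+1;if(R[i].y>ymax)ymax=R[i].y;}",
    " var mx=Math.max.apply(null,xb.concat([1]));XC.fillStyle='#4477aa';",
    " for(var b=0;b<360;b++){var h=xb[b]/mx*(XO.height-4);",
    "  XC.fillRect(b/360*XO.width,XO.height-h,XO.width/360,h);}",
    " XC.strokeStyle='#c44';XC.strokeRect(V.x0/360*XO.width,0,(V.x1-V.x0)/360*XO.width,XO.height);",
    " YC.clearRect(0,0,YO.width,YO.height);var my=1;",
    " Object.keys(yb).forEach(function(k){if(yb[k]>my)my=yb[k];});YC.fillStyle='#4477aa';",
    " Object.keys(yb).forEach(function(k){var y=+k,h=YO.height/ymax;",
    "  YC.fillRect(0,YO.height-y*h+h*0.1,yb[k]/my*(YO.width-4),h*0.8);});}",
    "function redraw(){draw();overviews();}",
    "var drag=null;",
    "M.addEventListener('mousedown',function(e){drag={x:e.offsetX,x0:V.x0,x1:V.x1};});",
    "window.addEventListener('mouseup',function(){drag=null;});",
    "M.addEventListener('mousemove',function(e){",
    " if(drag){var dx=(e.offsetX-drag.x)/M.width*(drag.x1-drag.x0);",
    "  V.x0=drag.x0-dx;V.x1=drag.x1-dx;redraw();return;}",
    " var tip=document.getElementById('tip'),best=null,bd=64;",
    " for(var i=0;i<R.length;i++){var r=R[i];",
    "  var d=Math.pow(px(r.x)-e.offsetX,2)+Math.pow(py(r.y)-e.offsetY,2);",
    "  if(d<bd){bd=d;best=r;}}",
    " if(best){var h=best.hover;tip.style.display='block';",
    "  tip.style.left=(e.clientX+12)+'px';tip.style.top=(e.clientY+12)+'px';",
    "  tip.textContent='pos '+h.rel_position.toFixed(2)+' | BitScore '+h.bitscore+",
    "   ' | '+h.query+' | '+h.organism+' | '+h.product;}",
    " else tip.style.display='none';});",
    "M.addEventListener('wheel',function(e){e.preventDefault();",
    " var f=e.deltaY<0?0.8:1.25,cx=V.x0+e.offsetX/M.width*(V.x1-V.x0);",
    " V.x0=cx-(cx-V.x0)*f;V.x1=cx+(V.x1-cx)*f;redraw();},{passive:false});",
    "M.addEventListener('click',function(e){",
    " if(drag&&Math.abs(e.offsetX-drag.x)>3)return;",
    " var best=null,bd=64;",
    " for(var i=0;i<R.length;i++){var r=R[i];",
    "  var d=Math.pow(px(r.x)-e.offsetX,2)+Math.pow(py(r.y)-e.offsetY,2);",
    "  if(d<bd){bd=d;best=r;}}",
    " if(best){var c=best.click,h=best.hover;",
    "  document.getElementById('detail').textContent=",
    "   'query: '+h.query+'\\nsubject: '+c.subject_id+'\\nreplicon: '+c.replicon_id+",
    "   '\\norganism: '+h.organism+'\\nproduct: '+h.product+",
    "   '\\nrel position: '+h.rel_position+'\\nBitScore: '+h.bitscore+",
    "   '\\nE-value: '+c.evalue+'\\nsubject coords: '+c.s_start+'..'+c.s_end;}});",
    "XO.addEventListener('mousedown',function(e){",
    " var a=e.offsetX/XO.width*360;",
    " function mv(ev){var b=ev.offsetX/XO.width*360;",
    "  V.x0=Math.max(0,Math.min(a,b));V.x1=Math.min(360,Math.max(a,b,V.x0+1));redraw();}",
    " function up(){XO.removeEventListener('mousemove',mv);window.removeEventListener('mouseup',up);}",
    " XO.addEventListener('mousemove',mv);window.addEventListener('mouseup',up);});",
    "YO.addEventListener('click',function(e){",
    " var ymax=1;for(var i=0;i<R.length;i++)if(R[i].y>ymax)ymax=R[i].y;",
    " var y=Math.max(1,Math.round((YO.height-e.offsetY)/YO.height*ymax));",
    " V.y0=Math.max(1,y-5);V.y1=y+5;redraw();});",
    "redraw();"
  ), collapse = "\n")
}

#' Write the spreadsheet table as an HTML page
#'
#' A plain sortable-by-eye table of the (filtered) results with the same
#' columns as the TSV export.
#'
#' @param results Plotted-result tibble.
#' @param path Output path.
#' @param title Page title.
#' @return `path`, invisibly.
#' @export
render_table_html <- function(results, path, title = "blastxy table") {
  check_results(results)
  rows <- tibble::as_tibble(results)
  cells <- sprintf(
    "<tr><td>%s</td><td>%s</td><td>%s</td><td>%s</td><td>%s</td><td>%s</td><td>%s</td><td>%s</td></tr>",
    svg_esc(rows$query_id), svg_esc(rows$subject_id), svg_esc(rows$organism),
    svg_esc(rows$replicon_id), fmt_num(rows$x), fmt_num(rows$bitscore),
    formatC(rows$evalue, format = "e", digits = 4), svg_esc(rows$product)
  )
  html <- c(
    "<!DOCTYPE html>",
    "<html><head><meta charset=\"utf-8\">",
    paste0("<title>", svg_esc(title), "</title>"),
    "<style>table{border-collapse:collapse;font:13px sans-serif}",
    "td,th{border:1px solid #999;padding:2px 6px}</style></head><body>",
    paste0("<h3>", svg_esc(title), "</h3>"),
    "<table><tr><th>Query</th><th>Subject</th><th>Organism</th><th>Replicon</th>",
    "<th>RelPosition</th><th>BitScore</th><th>Evalue</th><th>Product</th></tr>",
    cells,
    "</table></body></html>"
  )
  writeLines(html, path)
  invisible(path)
}

#' Plot projected results with ggplot2
#'
#' The in-R counterpart of the rendered graph: dots at the transcription
#' start, strand-aware vectors, and alignment segments coloured from yellow
#' (low bit score) to dark blue (high).
#'
#' @param object A `blastxy_results` tibble.
#' @param view Optional [view_spec()] restricting the window.
#' @param ... Unused.
#' @return A ggplot object.
#' @method autoplot blastxy_results
#' @export
autoplot.blastxy_results <- function(object, view = NULL, ...) {
  rows <- if (is.null(view)) object else select_view(object, view)
  rows <- tibble::as_tibble(rows)
  sgn <- ifelse(rows$vector_deg >= 0, 1, -1)
  rows$seg_x0 <- rows$x + sgn * rows$seg_offset_deg
  rows$seg_x1 <- rows$x + sgn * (rows$seg_offset_deg + rows$seg_len_deg)
  ggplot2::ggplot(rows, ggplot2::aes(x = .data$x, y = .data$y)) +
    ggplot2::geom_segment(ggplot2::aes(xend = .data$x + .data$vector_deg,
                                       yend = .data$y),
                          linewidth = 0.3, colour = "grey40") +
    ggplot2::geom_segment(ggplot2::aes(x = .data$seg_x0, xend = .data$seg_x1,
                                       yend = .data$y,
                                       colour = .data$bitscore),
                          linewidth = 1.2) +
    ggplot2::geom_point(size = 0.8) +
    ggplot2::scale_colour_gradient(low = "#FFFF00", high = "#00008B",
                                   name = "BitScore") +
    ggplot2::labs(x = "relative position (degrees)", y = "replicon") +
    ggplot2::theme_minimal()
}

#' @rdname autoplot.blastxy_results
#' @param results Plotted-result tibble.
#' @export
plot_results <- function(results, view = NULL, ...) {
  autoplot.blastxy_results(results, view = view, ...)
}
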