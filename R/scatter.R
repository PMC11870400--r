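# Self-contained interactive scatter export: one HTML file, no external
# assets. Points for the first min(3, k) ordination axes are embedded as a
# JSON block (id "metord-data") and rendered by a small inline SVG renderer
# with drag-to-rotate (when 3 axes are present) and per-group show/hide.

#' Export an interactive 3-D ordination scatter as standalone HTML
#'
#' Renders the first `min(3, k)` axes of an ordination into a single
#' self-contained HTML file: points colored by one metadata column,
#' optionally shaped by another, a legend that toggles each group on and off,
#' and axis labels carrying the proportion of variation explained. With three
#' axes the view can be rotated by dragging; with two it is a flat scatter.
#'
#' @param result a `metord_ord` ordination result.
#' @param metadata metadata data.frame covering the result's samples.
#' @param color_by metadata column used for point colors.
#' @param shape_by optional metadata column used for point shapes.
#' @param path output HTML path.
#' @param title plot title.
#' @return `path`, invisibly.
#' @export
render_scatter <- function(result, metadata, color_by, shape_by = NULL,
                           path, title = "PCoA") {
  stopifnot(inherits(result, "metord_ord"))
  for (col in c(color_by, shape_by)) {
    if (!col %in% colnames(metadata)) {
      stop(sprintf("column '%s' not in metadata; available: %s", col,
                   paste(colnames(metadata), collapse = ", ")), call. = FALSE)
    }
  }
  missing_ids <- setdiff(result$ids, rownames(metadata))
  if (length(missing_ids)) {
    stop("metadata lacks sample(s): ", paste(missing_ids, collapse = ", "),
         call. = FALSE)
  }
  k <- min(3L, ncol(result$coordinates))
  if (k < 1L) stop("ordination has no axes to render", call. = FALSE)
  coords <- result$coordinates[, seq_len(k), drop = FALSE]
  pts <- data.frame(
    id = result$ids,
    x = coords[, 1],
    y = if (k >= 2) coords[, 2] else 0,
    z = if (k >= 3) coords[, 3] else 0,
    color = as.character(metadata[result$ids, color_by]),
    shape = if (is.null(shape_by)) "all" else
      as.character(metadata[result$ids, shape_by]),
    stringsAsFactors = FALSE
  )
  axis_label <- function(a) {
    if (a > ncol(result$coordinates)) return("")
    sprintf("%s (%.1f%%)", colnames(result$coordinates)[a],
            100 * result$proportion_explained[a])
  }
  payload <- list(
    title = title,
    n_axes = k,
    axis_labels = vapply(seq_len(3), axis_label, character(1)),
    points = pts
  )
  json <- jsonlite::toJSON(payload, dataframe = "rows", auto_unbox = TRUE,
                           digits = NA)
  write_lines_safely(scatter_html(json), path)
  invisible(path)
}

scatter_html <- function(json) {
  c('<!DOCTYPE html>',
    '<html><head><meta charset="utf-8"><title>Ordination scatter</title>',
    '<style>',
    'body{font-family:sans-serif;margin:16px}',
    '#plot{border:1px solid #ccc;touch-action:none}',
    '#legend label{display:block;margin:2px 0;cursor:pointer}',
    '.swatch{display:inline-block;width:12px;height:12px;margin-right:6px;vertical-align:middle}',
    '#wrap{display:flex;gap:24px}',
    '</style></head><body>',
    '<script type="application/json" id="metord-data">',
    as.character(json),
    '</script>',
    '<div id="wrap"><div><h3 id="title"></h3>',
    '<svg id="plot" width="640" height="560"></svg>',
    '<p id="hint" style="color:#666;font-size:smaller"></p></div>',
    '<div><h4>Groups</h4><div id="legend"></div></div></div>',
    '<script>',
    'var DATA=JSON.parse(document.getElementById("metord-data").textContent);',
    'var PAL=["#1f77b4","#ff7f0e","#2ca02c","#d62728","#9467bd","#8c564b","#e377c2","#7f7f7f","#bcbd22","#17becf"];',
    'var SHAPES=["circle","square","triangle","diamond"];',
    'document.getElementById("title").textContent=DATA.title;',
    'var colorGroups=[],shapeGroups=[];',
    'DATA.points.forEach(function(p){',
    ' if(colorGroups.indexOf(p.color)<0)colorGroups.push(p.color);',
    ' if(shapeGroups.indexOf(p.shape)<0)shapeGroups.push(p.shape);});',
    'var visible={};colorGroups.forEach(function(g){visible[g]=true;});',
    'var yaw=0.5,pitch=0.4,drag=null;',
    'var svg=document.getElementById("plot"),W=640,H=560;',
    'function extent(a){var lo=Math.min.apply(null,a),hi=Math.max.apply(null,a);',
    ' if(hi-lo<1e-12){lo-=1;hi+=1;}return[lo,hi];}',
    'var ex=extent(DATA.points.map(function(p){return p.x;})),',
    '    ey=extent(DATA.points.map(function(p){return p.y;})),',
    '    ez=extent(DATA.points.map(function(p){return p.z;}));',
    'function norm(v,e){return (v-(e[0]+e[1])/2)/((e[1]-e[0])/2);}',
    'function project(p){',
    ' var x=norm(p.x,ex),y=norm(p.y,ey),z=norm(p.z,ez);',
    ' if(DATA.n_axes<3){return[ (x*0.45+0.5)*W, (0.5-y*0.45)*H, 0];}',
    ' var cy=Math.cos(yaw),sy=Math.sin(yaw),cp=Math.cos(pitch),sp=Math.sin(pitch);',
    ' var x1=cy*x+sy*z, z1=-sy*x+cy*z;',
    ' var y1=cp*y-sp*z1, z2=sp*y+cp*z1;',
    ' return[(x1*0.4+0.5)*W,(0.5-y1*0.4)*H,z2];}',
    'function marker(shape,cx,cy,col){',
    ' var s=5;',
    ' if(shape==="square")return \'<rect x="\'+(cx-s)+\'" y="\'+(cy-s)+\'" width="\'+(2*s)+\'" height="\'+(2*s)+\'" fill="\'+col+\'"/>\';',
    ' if(shape==="triangle")return \'<polygon points="\'+cx+\',\'+(cy-s)+\' \'+(cx-s)+\',\'+(cy+s)+\' \'+(cx+s)+\',\'+(cy+s)+\'" fill="\'+col+\'"/>\';',
    ' if(shape==="diamond")return \'<polygon points="\'+cx+\',\'+(cy-s)+\' \'+(cx+s)+\',\'+cy+\' \'+cx+\',\'+(cy+s)+\' \'+(cx-s)+\',\'+cy+\'" fill="\'+col+\'"/>\';',
    ' return \'<circle cx="\'+cx+\'" cy="\'+cy+\'" r="\'+s+\'" fill="\'+col+\'"/>\';}',
    'function render(){',
    ' var parts=[];',
    ' parts.push(\'<text x="8" y="\'+(H-8)+\'" font-size="12">\'+DATA.axis_labels[0]+\'</text>\');',
    ' if(DATA.n_axes>1)parts.push(\'<text x="8" y="16" font-size="12">\'+DATA.axis_labels[1]+\'</text>\');',
    ' if(DATA.n_axes>2)parts.push(\'<text x="\'+(W-160)+\'" y="16" font-size="12">\'+DATA.axis_labels[2]+\'</text>\');',
    ' var drawn=DATA.points.filter(function(p){return visible[p.color];})',
    '  .map(function(p){var q=project(p);',
    '   return{p:p,sx:q[0],sy:q[1],depth:q[2]};});',
    ' drawn.sort(function(a,b){return a.depth-b.depth;});',
    ' drawn.forEach(function(d){',
    '  var col=PAL[colorGroups.indexOf(d.p.color)%PAL.length];',
    '  var sh=SHAPES[shapeGroups.indexOf(d.p.shape)%SHAPES.length];',
    '  parts.push(\'<g class="pt">\'+marker(sh,d.sx,d.sy,col)+\'<title>\'+d.p.id+\'</title></g>\');});',
    ' svg.innerHTML=parts.join("");}',
    'function buildLegend(){',
    ' var div=document.getElementById("legend");',
    ' colorGroups.forEach(function(g,i){',
    '  var lab=document.createElement("label");',
    '  var cb=document.createElement("input");cb.type="checkbox";cb.checked=true;',
    '  cb.addEventListener("change",function(){visible[g]=cb.checked;render();});',
    '  var sw=document.createElement("span");sw.className="swatch";',
    '  sw.style.background=PAL[i%PAL.length];',
    '  lab.appendChild(cb);lab.appendChild(sw);',
    '  lab.appendChild(document.createTextNode(g));div.appendChild(lab);});',
    ' if(shapeGroups.length>1){',
    '  var h=document.createElement("h4");h.textContent="Shapes";div.appendChild(h);',
    '  shapeGroups.forEach(function(g,i){',
    '   var lab=document.createElement("div");',
    '   lab.textContent=SHAPES[i%SHAPES.length]+": "+g;div.appendChild(lab);});}}',
    'if(DATA.n_axes>2){',
    ' document.getElementById("hint").textContent="Drag to rotate.";',
    ' svg.addEventListener("pointerdown",function(e){drag=[e.clientX,e.clientY];});',
    ' window.addEventListener("pointerup",function(){drag=null;});',
    ' window.addEventListener("pointermove",function(e){',
    '  if(!drag)return;yaw+=(e.clientX-drag[0])*0.01;pitch+=(e.clientY-drag[1])*0.01;',
    '  drag=[e.clientX,e.clientY];render();});}',
    'buildLegend();render();',
    '</script></body></html>')
}
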