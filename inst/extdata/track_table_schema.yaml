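# Schema of the long-format trajectory table accepted by read_trackset()
# (CSV by default; .tsv/.tab for tab-delimited). One row per individual
# per frame. Units of x/y are set by the arena config's px_per_mm
# (1 means already mm); heading is radians, any branch.
columns:
  id:          {type: string,  required: true,  doc: individual identity label}
  frame:       {type: integer, required: true,  doc: 0-based frame index, strictly increasing per id}
  x:           {type: number,  required: true,  doc: center x position (px or mm)}
  y:           {type: number,  required: true,  doc: center y position (px or mm), origin lower-left, y up}
  heading:     {type: number,  required: true,  doc: body-axis orientation, radians}
  body_length: {type: number,  required: false, doc: per-frame posture length (px or mm); consolidated per id by median}
constraints:
  - (id, frame) pairs are unique
  - frames an individual is missing are treated as tracking gaps, never interpolated
  - valid positions lie inside the arena rectangle up to a wall-contact tolerance
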