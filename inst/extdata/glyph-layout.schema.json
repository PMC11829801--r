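{
  "$schema": "http://json-schema.org/draft-07/schema#",
  "title": "Glyph layout geometry",
  "description": "Renderer-independent geometry of a scatter-bar or scatter-pie glyph map: per-location, per-category rectangles or wedges with the resolved sizing. Angles are degrees, clockwise from 12 o'clock; coordinates are plot units with y up.",
  "type": "object",
  "required": ["glyph_kind", "sizing", "categories", "segments", "bbox"],
  "properties": {
    "glyph_kind": { "type": "string", "enum": ["bar", "pie"] },
    "sizing": {
      "type": "object",
      "required": ["size_x", "size_y", "padding_x", "padding_y", "auto_x", "auto_y"],
      "properties": {
        "size_x": { "type": "number" },
        "size_y": { "type": "number" },
        "padding_x": { "type": "number" },
        "padding_y": { "type": "number" },
        "auto_x": { "type": "boolean" },
        "auto_y": { "type": "boolean" }
      }
    },
    "categories": { "type": "array", "items": { "type": "string" } },
    "segments": {
      "type": "array",
      "items": {
        "type": "object",
        "required": ["location", "category", "proportion"],
        "properties": {
          "location": { "type": "string" },
          "category": { "type": "string" },
          "proportion": { "type": "number" },
          "x_left": { "type": "number" },
          "x_right": { "type": "number" },
          "y_bottom": { "type": "number" },
          "y_top": { "type": "number" },
          "center_x": { "type": "number" },
          "center_y": { "type": "number" },
          "radius": { "type": "number" },
          "theta_start": { "type": "number" },
          "theta_end": { "type": "number" }
        }
      }
    },
    "bbox": {
      "type": "object",
      "required": ["x_min", "x_max", "y_min", "y_max"],
      "properties": {
        "x_min": { "type": "number" },
        "x_max": { "type": "number" },
        "y_min": { "type": "number" },
        "y_max": { "type": "number" }
      }
    }
  }
}
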