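{
  "$schema": "http://json-schema.org/draft-07/schema#",
  "title": "Diseasome vis-network payload",
  "description": "Node-link payload for an interactive network renderer. Node value is the display size sqrt(n)*0.3+2.5; edge width is m*0.01; titles are tooltip strings.",
  "type": "object",
  "required": ["nodes", "edges"],
  "properties": {
    "nodes": {
      "type": "array",
      "items": {
        "type": "object",
        "required": ["id", "label", "value", "color", "title"],
        "properties": {
          "id": {"type": "string"},
          "label": {"type": "string"},
          "value": {"type": "number", "minimum": 2.5},
          "color": {"type": "string"},
          "title": {"type": "string"}
        }
      }
    },
    "edges": {
      "type": "array",
      "items": {
        "type": "object",
        "required": ["from", "to", "width", "title"],
        "properties": {
          "id": {"type": "string"},
          "from": {"type": "string"},
          "to": {"type": "string"},
          "width": {"type": "number", "minimum": 0},
          "title": {"type": "string"}
        }
      }
    }
  }
}
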