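{
  "$schema": "https://json-schema.org/draft/2020-12/schema",
  "$id": "venusscore/questionnaire.schema.json",
  "title": "Venus questionnaire schema",
  "description": "Serialized form of a Venus-style scoring instrument. Each question is worth one point; its sub-item weights are nonnegative and sum to 1. load_questionnaire() enforces the same constraints natively.",
  "type": "object",
  "required": ["name", "version", "questions"],
  "properties": {
    "name": { "type": "string" },
    "version": { "type": "string" },
    "questions": {
      "type": "array",
      "minItems": 1,
      "items": {
        "type": "object",
        "required": ["id", "sub_items"],
        "properties": {
          "id": { "type": "string", "pattern": "^Q[0-9]+$" },
          "title": { "type": "string" },
          "guidance": { "type": "string" },
          "sub_items": {
            "type": "array",
            "minItems": 1,
            "items": {
              "type": "object",
              "required": ["id", "weight"],
              "properties": {
                "id": { "type": "string" },
                "label": { "type": "string" },
                "weight": { "type": "number", "minimum": 0 }
              }
            }
          }
        }
      }
    }
  }
}
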