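{
  "when": {
    "level1": ["now", "anytime", "any time", "today", "tomorrow", "vague time"],
    "level2": ["every hour", "after lunch", "after dinner", "after lecture",
               "after meeting", "every morning", "every evening", "in between",
               "between lectures", "every 30 min", "every day"],
    "level2_patterns": ["\\bevery\\b", "\\bafter\\b", "\\bbefore\\b", "\\bduring\\b"],
    "level3_patterns": ["\\b[0-2]?[0-9]:[0-5][0-9]\\b", "\\b[0-1]?[0-9]\\s*(am|pm)\\b"]
  },
  "where": {
    "level1": ["out", "outside", "anywhere"],
    "level2": ["city", "university", "campus", "outdoor", "town"],
    "level3": ["post", "lab", "office", "home", "library", "dormitory",
               "kitchen", "park", "garden", "building", "gym", "supermarket",
               "workplace"]
  },
  "how": {
    "level2_patterns": ["\\bgoing to\\b", "\\bgo to\\b", "\\bget out\\b"],
    "level3": ["walk", "walking", "yoga", "cycle", "cycling", "push-ups",
               "push ups", "pushups", "stretch", "stand up", "stand",
               "jump", "jumping", "run", "running", "steps", "squats",
               "stairs", "get up"]
  }
}
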