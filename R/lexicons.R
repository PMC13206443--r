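# Built-in food lexicons: ingredient categories, dish names, health
# concepts and their promoted ingredients, taste words, and the default
# intent lexicon. Shipped as code so the package is self-contained; all
# names are pre-normalized (lowercase singular).

#' Default ingredient ontology
#'
#' Category -> member ingredient sets used for category-aware exclusion
#' ("no nuts" must veto a recipe containing peanuts) and for diet-tag
#' rules (vegan excludes all animal-derived categories). Editable: pass
#' your own ontology of the same shape to [hard_filter()].
#'
#' @return List with elements `categories` (named list of character
#'   vectors) and `diet_rules` (diet tag -> excluded category names).
#' @export
default_ontology <- function() {
  categories <- list(
    nuts      = c("peanut", "almond", "walnut", "cashew", "pecan",
                  "hazelnut", "pistachio"),
    dairy     = c("milk", "butter", "cheese", "cream", "yogurt"),
    gluten    = c("wheat flour", "bread", "pasta", "barley", "rye",
                  "couscous", "noodle"),
    shellfish = c("shrimp", "crab", "lobster", "scallop", "clam",
                  "mussel"),
    meat      = c("chicken", "beef", "pork", "lamb", "turkey", "bacon",
                  "ham", "sausage"),
    fish      = c("salmon", "tuna", "cod", "trout", "sardine"),
    egg       = c("egg"),
    vegetable = c("broccoli", "spinach", "kale", "carrot", "onion",
                  "garlic", "tomato", "bell pepper", "zucchini",
                  "cauliflower", "mushroom", "cabbage", "sweet potato",
                  "potato", "cucumber", "celery", "beet", "pea",
                  "green bean"),
    fruit     = c("apple", "banana", "orange", "lemon", "blueberry",
                  "strawberry", "mango", "avocado", "pineapple",
                  "grape"),
    grain     = c("rice", "quinoa", "oat", "corn", "buckwheat",
                  "millet"),
    legume    = c("lentil", "chickpea", "black bean", "kidney bean",
                  "tofu", "edamame"),
    spice     = c("turmeric", "ginger", "basil", "cilantro", "parsley",
                  "cumin", "paprika", "chili", "cinnamon",
                  "black pepper", "oregano", "rosemary", "thyme",
                  "mint"),
    oil       = c("olive oil", "coconut oil", "sesame oil"),
    sweetener = c("honey", "sugar", "maple syrup")
  )
  diet_rules <- list(
    vegan       = c("meat", "fish", "shellfish", "dairy", "egg"),
    vegetarian  = c("meat", "fish", "shellfish"),
    pescatarian = c("meat"),
    gluten_free = c("gluten"),
    dairy_free  = c("dairy"),
    nut_free    = c("nuts")
  )
  list(categories = categories, diet_rules = diet_rules)
}

all_ingredient_names <- function(ontology = default_ontology()) {
  sort(unique(unlist(ontology$categories, use.names = FALSE)))
}

# short dish names recognised by the query classifier
.dish_names <- c(
  "pizza", "burger", "lasagna", "taco", "curry", "stew", "soup",
  "salad", "risotto", "omelette", "pancake", "sandwich", "sushi",
  "ramen", "paella", "chili", "smoothie", "stir fry", "casserole",
  "frittata", "wrap", "bowl", "pasta", "noodle"
)

#' Health-concept map
#'
#' Named list: health concept -> list(promotes = concept names,
#' ingredients = promoted ingredient names). These seed the food
#' knowledge graph's concept layer; the immune-support chain
#' (immune_system -> anti_inflammatory -> turmeric/ginger/garlic) is the
#' canonical two-hop bridge from an abstract goal to concrete
#' ingredients.
#'
#' @return Named list of concept definitions.
#' @export
health_concepts <- function() {
  list(
    immune_system     = list(promotes = "anti_inflammatory",
                             ingredients = c("garlic", "ginger",
                                             "orange", "spinach")),
    anti_inflammatory = list(promotes = character(),
                             ingredients = c("turmeric", "ginger",
                                             "garlic", "salmon")),
    heart_health      = list(promotes = character(),
                             ingredients = c("salmon", "oat",
                                             "olive oil", "walnut")),
    muscle_building   = list(promotes = character(),
                             ingredients = c("chicken", "egg", "tofu",
                                             "lentil")),
    muscle_recovery   = list(promotes = "muscle_building",
                             ingredients = c("salmon", "egg",
                                             "banana")),
    weight_loss       = list(promotes = character(),
                             ingredients = c("broccoli", "spinach",
                                             "cucumber", "cauliflower")),
    gut_health        = list(promotes = character(),
                             ingredients = c("yogurt", "oat", "banana",
                                             "kale")),
    energy_boost      = list(promotes = character(),
                             ingredients = c("oat", "banana", "quinoa",
                                             "sweet potato")),
    bone_health       = list(promotes = character(),
                             ingredients = c("milk", "kale", "tofu")),
    brain_health      = list(promotes = "antioxidant",
                             ingredients = c("salmon", "walnut",
                                             "blueberry")),
    skin_health       = list(promotes = character(),
                             ingredients = c("avocado", "carrot",
                                             "sweet potato")),
    iron_rich         = list(promotes = character(),
                             ingredients = c("spinach", "lentil",
                                             "beef")),
    antioxidant       = list(promotes = character(),
                             ingredients = c("blueberry", "kale",
                                             "beet")),
    low_glycemic      = list(promotes = character(),
                             ingredients = c("lentil", "quinoa",
                                             "broccoli")),
    quick_meal        = list(promotes = character(),
                             ingredients = c("egg", "pasta", "tofu",
                                             "shrimp")),
    family_friendly   = list(promotes = character(),
                             ingredients = c("pasta", "chicken", "rice",
                                             "cheese"))
  )
}

#' Concept lexicon: query phrase -> graph concept node
#'
#' Maps health/intent phrases occurring in user queries to concept node
#' names of the food knowledge graph.
#'
#' @return Named character vector (phrase -> concept name).
#' @export
default_concept_lexicon <- function() {
  c("immune boosting"  = "immune_system",
    "immune-boosting"  = "immune_system",
    "immunity"         = "immune_system",
    "immune"           = "immune_system",
    "anti inflammatory" = "anti_inflammatory",
    "anti-inflammatory" = "anti_inflammatory",
    "heart healthy"    = "heart_health",
    "heart health"     = "heart_health",
    "muscle building"  = "muscle_building",
    "muscle-building"  = "muscle_building",
    "post workout"     = "muscle_recovery",
    "post-workout"     = "muscle_recovery",
    "recovery"         = "muscle_recovery",
    "weight loss"      = "weight_loss",
    "slimming"         = "weight_loss",
    "gut health"       = "gut_health",
    "digestion"        = "gut_health",
    "energy boost"     = "energy_boost",
    "energizing"       = "energy_boost",
    "bone health"      = "bone_health",
    "brain health"     = "brain_health",
    "brain food"       = "brain_health",
    "skin health"      = "skin_health",
    "glowing skin"     = "skin_health",
    "iron rich"        = "iron_rich",
    "iron-rich"        = "iron_rich",
    "antioxidant"      = "antioxidant",
    "low glycemic"     = "low_glycemic",
    "quick"            = "quick_meal",
    "weeknight"        = "quick_meal",
    "family"           = "family_friendly")
}

# taste/craving word -> signature ingredient (used by the synthetic
# benchmark generator and the intent lexicon)
.taste_map <- c(
  spicy    = "chili",
  sweet    = "honey",
  tangy    = "lemon",
  garlicky = "garlic",
  creamy   = "cream",
  minty    = "mint",
  smoky    = "paprika"
)

#' Default intent lexicon
#'
#' Phrase -> partial constraint fragment used by the deterministic
#' rule-based intent refiner. Fragments are merged by [refine_intent()];
#' conflicting macro bounds resolve to the tighter bound.
#'
#' @return Named list: lowercase phrase -> constraint fragment (a list
#'   with any of the `constraint_set()` fields).
#' @export
default_intent_lexicon <- function() {
  frag <- function(...) list(...)
  lex <- list(
    "light"           = frag(macro = list(calories = list(max = 600))),
    "low calorie"     = frag(macro = list(calories = list(max = 500))),
    "low-calorie"     = frag(macro = list(calories = list(max = 500))),
    "filling"         = frag(macro = list(protein = list(min = 20))),
    "high protein"    = frag(macro = list(protein = list(min = 20))),
    "high-protein"    = frag(macro = list(protein = list(min = 20))),
    "protein packed"  = frag(macro = list(protein = list(min = 20))),
    "low carb"        = frag(macro = list(carbohydrates = list(max = 30))),
    "low-carb"        = frag(macro = list(carbohydrates = list(max = 30))),
    "low fat"         = frag(macro = list(fat = list(max = 15))),
    "low-fat"         = frag(macro = list(fat = list(max = 15))),
    "high fiber"      = frag(macro = list(fiber = list(min = 5))),
    "high-fiber"      = frag(macro = list(fiber = list(min = 5))),
    "breakfast"       = frag(course = "breakfast"),
    "lunch"           = frag(course = "lunch"),
    "dinner"          = frag(course = "dinner"),
    "snack"           = frag(course = "snack"),
    "dessert"         = frag(course = "dessert"),
    "vegan"           = frag(diet_tags = "vegan"),
    "vegetarian"      = frag(diet_tags = "vegetarian"),
    "pescatarian"     = frag(diet_tags = "pescatarian"),
    "gluten free"     = frag(diet_tags = "gluten_free"),
    "gluten-free"     = frag(diet_tags = "gluten_free"),
    "dairy free"      = frag(diet_tags = "dairy_free"),
    "dairy-free"      = frag(diet_tags = "dairy_free"),
    "nut free"        = frag(exclude = "nuts"),
    "nut-free"        = frag(exclude = "nuts"),
    "nut allergy"     = frag(exclude = "nuts"),
    "immune boosting" = frag(health_goals = "immune_boosting"),
    "immune-boosting" = frag(health_goals = "immune_boosting"),
    "immunity"        = frag(health_goals = "immune_boosting"),
    "post workout"    = frag(health_goals = "muscle_recovery",
                             macro = list(protein = list(min = 20))),
    "post-workout"    = frag(health_goals = "muscle_recovery",
                             macro = list(protein = list(min = 20))),
    "muscle building" = frag(health_goals = "muscle_building",
                             macro = list(protein = list(min = 20))),
    "weight loss"     = frag(health_goals = "weight_loss",
                             macro = list(calories = list(max = 600))),
    "heart healthy"   = frag(health_goals = "heart_health"),
    "quick"           = frag(health_goals = "quick_meal"),
    "weeknight"       = frag(health_goals = "quick_meal"),
    "family"          = frag(health_goals = "family_friendly")
  )
  # taste cravings translate to mandatory signature ingredients
  for (w in names(.taste_map)) lex[[w]] <- frag(include = .taste_map[[w]])
  lex
}

# abstract-goal marker words (Eq.-2-style intent cues) beyond the full
# lexicon phrases; any hit classifies a query as intent-bearing
.intent_markers <- c(
  "healthy", "nutritious", "wholesome", "boosting", "recovery",
  "energizing", "immunity", "slimming", "detox"
)
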