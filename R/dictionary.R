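# Internal word and name pools. The dictionary backs both the synthetic
# free-text generator and the free-text plausibility evaluator; keeping them
# on a shared vocabulary is what lets the evaluator be validated against the
# generator's latent plausibility labels.

.ft_dictionary <- c(
  "a", "i", "the", "an", "and", "or", "but", "also", "at", "in", "on", "of",
  "to", "for", "with", "by", "from", "as", "is", "are", "was", "were", "be",
  "been", "have", "has", "had", "do", "does", "did", "not", "no", "yes",
  "we", "our", "my", "their", "this", "that", "these", "those", "it", "its",
  "provide", "provided", "providing", "offer", "offered", "offering",
  "work", "worked", "working", "practice", "practices", "practising",
  "clinic", "clinics", "clinical", "hospital", "hospitals", "community",
  "rural", "remote", "urban", "regional", "local", "second", "first",
  "other", "another", "additional", "extra", "further", "more", "most",
  "care", "service", "services", "patient", "patients", "client", "clients",
  "abortion", "contraception", "contraceptive", "pregnancy", "pregnant",
  "procedural", "medical", "medication", "surgical", "counselling",
  "referral", "referrals", "refer", "insertion", "insertions", "implant",
  "implants", "device", "devices", "injection", "injections", "telehealth",
  "consult", "consults", "consultation", "consultations", "follow", "up",
  "visit", "visits", "appointment", "appointments", "week", "weeks",
  "month", "months", "year", "years", "day", "days", "time", "times",
  "part", "full", "about", "around", "approximately", "mainly", "mostly",
  "occasionally", "sometimes", "often", "usually", "currently", "recently",
  "during", "after", "before", "since", "when", "where", "because",
  "training", "trained", "supervision", "teaching", "research", "team",
  "nurse", "nurses", "doctor", "doctors", "physician", "physicians",
  "midwife", "pharmacist", "specialist", "registrar", "locum", "staff",
  "health", "centre", "center", "region", "area", "town", "city",
  "province", "state", "travel", "travelling", "cover", "covering",
  "support", "supporting", "supported", "program", "programs", "role",
  "roles", "position", "private", "public", "family", "general",
  "medicine", "gynaecology", "obstetrics", "women", "youth", "young",
  "people", "population", "access", "available", "availability", "limited",
  "small", "large", "busy", "only", "once", "twice", "per", "each", "some",
  "all", "both", "few", "many", "several", "number", "based", "see", "seen",
  "take", "takes", "taking", "use", "used", "using", "help", "helping",
  "needed", "required", "requested", "prefer", "preferred", "option",
  "options", "answer", "answered", "question", "questions", "survey",
  "including", "include", "included", "range", "types", "type"
)

.first_names <- c(
  "jane", "emily", "sarah", "laura", "claire", "megan", "olivia", "sophie",
  "hannah", "grace", "amelia", "chloe", "priya", "mei", "fatima", "aisha",
  "ingrid", "nadia", "carmen", "lucia", "james", "david", "michael",
  "robert", "thomas", "daniel", "matthew", "andrew", "peter", "paul",
  "simon", "mark", "liam", "noah", "ethan", "arjun", "wei", "omar",
  "carlos", "stefan"
)

.last_names <- c(
  "smith", "jones", "taylor", "brown", "wilson", "campbell", "martin",
  "thompson", "white", "anderson", "walker", "harris", "clark", "lewis",
  "young", "king", "wright", "scott", "green", "baker", "hill", "adams",
  "nelson", "carter", "mitchell", "roberts", "turner", "phillips", "parker",
  "evans", "collins", "stewart", "morris", "murphy", "cook", "rogers",
  "reed", "bailey", "bell", "cox"
)

.trusted_domains <- c("ubc.ca", "monash.edu", "utoronto.ca", "unimelb.edu.au",
                      "healthauthority.org")
.generic_domains <- c("gmail.com", "outlook.com", "yahoo.com", "hotmail.com")
.suspicious_domains <- c("mail.com", "inbox.net", "qq.com")
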