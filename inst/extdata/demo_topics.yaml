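# Example seeded-topic configuration: ten supervised topics with seed words.
# The tenth topic ("future") is a user-defined placeholder; production seed
# lists are study-specific.
assignment_threshold: 0.2
topics: [treatment, family, sleep, sex, school, death, substance_use, eating, friends, future]
seed_words:
  treatment: [therapy, therapist, medication, meds, psychiatrist, counseling, appointment, prescription]
  family: [mom, dad, brother, sister, grandma, grandpa, cousin, parents]
  sleep: [insomnia, nap, bedtime, pillow, dreams, awake, oversleep, melatonin]
  sex: [sexting, hookup, crush, dating, flirting, boyfriend, girlfriend, situationship]
  school: [homework, exam, teacher, classroom, grades, quiz, semester, algebra]
  death: [funeral, grave, coffin, cemetery, afterlife, obituary, burial, mourning]
  substance_use: [weed, vape, alcohol, drunk, edibles, nicotine, stoned, vodka]
  eating: [calories, snack, dinner, breakfast, lunch, appetite, recipe, vegetarian]
  friends: [bestie, squad, hangout, sleepover, groupchat, classmates, buddies, pals]
  future: [college, career, internship, moving, apartment, roadtrip, graduation, gapyear]
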