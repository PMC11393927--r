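da
du
er
es
im
in
ja
so
wo
am
an
der
die
das
und
ist
mit
ein
als
aus
bei
bis
hat
was
wer
wie
nun
vor
zum
den
dem
man
mal
nur
oft
rot
tag
tun
gut
hin
her
neu
see
tee
eis
arm
ort
uhr
haus
kind
hund
wort
buch
baum
brot
ball
bett
berg
bild
blau
boot
dorf
ende
esel
fest
gabe
gans
gras
hand
herz
hose
igel
jahr
kalt
korb
kuh
lamm
land
laut
lied
loch
mond
mund
nase
nest
oma
opa
ohr
rad
ring
rose
salz
sand
satz
see
seil
sohn
sonne
stadt
stein
stern
stuhl
suppe
tafel
tante
tasse
teller
tiger
tisch
topf
torte
traum
tuer
vogel
wagen
wald
wand
wasser
weg
welt
wiese
wind
winter
wolke
zahl
zahn
zelt
ziege
zug
apfel
blume
brief
butter
donner
drache
ecke
fahne
feder
feld
fisch
flasche
garten
gesicht
glas
gold
hafen
haken
hase
heft
himmel
honig
insel
jacke
kaffee
kamel
kanne
karte
katze
keller
kerze
kiste
klasse
kleid
knopf
koffer
kopf
kreide
kreis
kuchen
lampe
leiter
leben
lesen
loewe
luft
maler
mantel
mauer
maus
messer
milch
morgen
mutter
nacht
nadel
nebel
onkel
papier
pferd
pilz
puppe
regen
reise
sache
schaf
schiff
schnee
schrank
schule
schuh
sommer
spiegel
spiel
sprache
strasse
tasche
teich
wecker
zange
zimmer
zucker
zunge
abenteuer
bibliothek
birnbaum
blumenwiese
computer
elefant
fahrrad
familie
fenster
freundin
gemuese
geburtstag
geschenk
geschichte
gespenst
giraffe
grossvater
handschuh
herbstwind
kalender
kartoffel
kaninchen
lehrerin
maschine
melodie
monster
nachmittag
pinguin
regenbogen
schmetterling
schokolade
schwester
spielplatz
teekanne
telefon
tomaten
werkstatt
wohnung
zeitung
zitrone
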