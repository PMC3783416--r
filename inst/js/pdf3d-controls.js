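// Control script attached to every 3-d figure. Runs inside the viewer's
// 3-d JavaScript context on instantiation. Provides:
//  - keyboard bindings: 1-7 recall the named views, +/- zoom, [/] roll,
//    arrows swing the camera, </> change the movement delta, Shift-A
//    toggles autospin, / and * change autospin speed;
//  - billboard handling: model-tree leaves whose names begin with
//    "BILLBOARD" are re-oriented to face the camera before every redraw;
//  - slice-set selection: of the groups named vrset_X1, vrset_Y1, vrset_Z1,
//    only the one most aligned with the camera view direction is visible.

var VIEW_KEYS = "1234567";
var delta = 0.1;
var autospin = false;
var spinSpeed = 1.0;

function vecSub(a, b) { return [a[0]-b[0], a[1]-b[1], a[2]-b[2]]; }
function vecDot(a, b) { return a[0]*b[0] + a[1]*b[1] + a[2]*b[2]; }
function vecLen(a) { return Math.sqrt(vecDot(a, a)); }

function findNode(name) {
  for (var i = 0; i < scene.nodes.count; i++)
    if (scene.nodes.getByIndex(i).name == name) return scene.nodes.getByIndex(i);
  return null;
}

function activeSliceAxis(camera) {
  var d = vecSub(camera.targetPosition, camera.position);
  var n = vecLen(d);
  var ax = [Math.abs(d[0]/n), Math.abs(d[1]/n), Math.abs(d[2]/n)];
  if (ax[0] >= ax[1] && ax[0] >= ax[2]) return 0;
  if (ax[1] >= ax[2]) return 1;
  return 2;
}

function updateSliceSets() {
  var names = ["vrset_X1", "vrset_Y1", "vrset_Z1"];
  var active = activeSliceAxis(scene.cameras.getByIndex(0));
  for (var i = 0; i < 3; i++) {
    var node = findNode(names[i]);
    if (node) node.visible = (i == active);
  }
}

function orientBillboards() {
  var cam = scene.cameras.getByIndex(0);
  for (var i = 0; i < scene.nodes.count; i++) {
    var node = scene.nodes.getByIndex(i);
    if (node.name.indexOf("BILLBOARD") != 0) continue;
    // minimal rotation taking the node's +z onto the node-to-camera
    // direction; translation (node centre) is preserved
    var c = node.transform.translation;
    var d = vecSub(cam.position, [c.x, c.y, c.z]);
    var n = vecLen(d);
    if (n > 0) node.transform.setView([d[0]/n, d[1]/n, d[2]/n], [0, 0, 1]);
  }
}

runtime.addEventHandler(new RenderEventHandler());
function RenderEventHandler() {
  this.onEvent = function(event) {
    orientBillboards();
    updateSliceSets();
    event.canvas.pivot.enable = true;
  };
}

runtime.addEventHandler(new KeyEventHandler());
function KeyEventHandler() {
  this.onEvent = function(event) {
    var ch = String.fromCharCode(event.characterCode);
    var cam = scene.cameras.getByIndex(0);
    var vk = VIEW_KEYS.indexOf(ch);
    if (vk >= 0 && vk < runtime.getViewCount()) {
      runtime.setView(runtime.getView(vk).name, vk);
    } else if (ch == "+") { cam.roo = cam.roo * (1 - delta); }
    else if (ch == "-") { cam.roo = cam.roo * (1 + delta); }
    else if (ch == "[") { cam.roll(-5 * delta * 10); }
    else if (ch == "]") { cam.roll(5 * delta * 10); }
    else if (ch == "<") { delta = Math.max(delta / 2, 0.0125); }
    else if (ch == ">") { delta = Math.min(delta * 2, 0.8); }
    else if (ch == "A") { autospin = !autospin; runtime.setAnimating(autospin); }
    else if (ch == "/") { spinSpeed = Math.max(spinSpeed / 2, 0.125); }
    else if (ch == "*") { spinSpeed = Math.min(spinSpeed * 2, 8); }
  };
}
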